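# Homoeo-SNP index: site calling from two diploid pileups, SNP-type
# classification, summary statistics, serialization, GSNAP/VCF export,
# and iterative merging.

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

allele_split <- function(x) strsplit(x, ",", fixed = TRUE)
allele_join <- function(x) paste(sort(x), collapse = ",")

#' Construct a homoeo-SNP index
#'
#' An index is a per-chromosome, position-sorted table with at most one
#' record per reference position. Allele sets of the two subgenomes must
#' be disjoint at every record: a shared base cannot discriminate the
#' genomes and would poison read categorization.
#'
#' @param records data.table (or data.frame) with columns chrom,
#'   pos (0-based integer), ref_base, alleles_A, alleles_D (comma-joined
#'   base sets), snp_type, and optionally origin.
#' @param reference Name of the reference the coordinates live on.
#' @param min_coverage,maf_threshold,fixation_threshold Build parameters
#'   recorded as metadata.
#' @return Object of class `snp_index` (a keyed data.table).
#' @export
snp_index <- function(records = NULL, reference = "unknown",
                      min_coverage = 4L, maf_threshold = 0.4,
                      fixation_threshold = 0.9) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.table(chrom = character(), pos = integer(),
                          ref_base = character(), alleles_A = character(),
                          alleles_D = character(), snp_type = character(),
                          origin = character())
  } else {
    records <- as.data.table(records)
    if (!"origin" %in% names(records)) records[, origin := "diploid_pileup"]
    records <- records[, .(chrom = as.character(chrom),
                           pos = as.integer(pos),
                           ref_base = toupper(ref_base),
                           alleles_A = toupper(alleles_A),
                           alleles_D = toupper(alleles_D),
                           snp_type = as.character(snp_type),
                           origin = as.character(origin))]
    setorder(records, chrom, pos)
    dup <- records[, .N, by = .(chrom, pos)][N > 1L]
    if (nrow(dup)) {
      hs_data_error("duplicate index position %s:%d", dup$chrom[1L],
                    dup$pos[1L] + 1L)
    }
    aA <- allele_split(records$alleles_A)
    aD <- allele_split(records$alleles_D)
    shared <- mapply(function(a, d) length(intersect(a, d)) > 0L, aA, aD)
    if (any(shared)) {
      w <- which(shared)[1L]
      hs_data_error("allele sets intersect at %s:%d", records$chrom[w],
                    records$pos[w] + 1L)
    }
  }
  setkey(records, chrom, pos)
  setattr(records, "class", c("snp_index", class(records)))
  setattr(records, "metadata",
          list(reference = reference, min_coverage = as.integer(min_coverage),
               maf_threshold = maf_threshold,
               fixation_threshold = fixation_threshold))
  records
}

#' @export
print.snp_index <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("homoeo-SNP index: %d records on reference '%s'\n",
              nrow(x), md$reference))
  cat(sprintf("  parameters: min_coverage=%d maf=%.2f fixation=%.2f\n",
              md$min_coverage, md$maf_threshold, md$fixation_threshold))
  if (nrow(x)) print(utils::head(as.data.table(x), 5L))
  invisible(x)
}

#' Classify a homoeo-SNP by its allele pair
#'
#' Single-base pairs are transitions when the two alleles are both
#' purines ({A,G}) or both pyrimidines ({C,T}), transversions otherwise.
#' A record where either genome carries more than one allele is
#' `multi_allele` and is excluded from the transition/transversion
#' tally.
#'
#' @param alleles_A,alleles_D Character vectors (or comma-joined
#'   strings) of the allele sets; must be disjoint and non-empty.
#' @return One of "transition", "transversion", "multi_allele".
#' @export
classify_snp <- function(alleles_A, alleles_D) {
  if (length(alleles_A) == 1L && grepl(",", alleles_A, fixed = TRUE))
    alleles_A <- allele_split(alleles_A)[[1L]]
  if (length(alleles_D) == 1L && grepl(",", alleles_D, fixed = TRUE))
    alleles_D <- allele_split(alleles_D)[[1L]]
  if (length(alleles_A) == 0L || length(alleles_D) == 0L) {
    hs_data_error("classify_snp: empty allele set")
  }
  if (length(intersect(alleles_A, alleles_D)) > 0L) {
    hs_data_error("classify_snp: allele sets overlap")
  }
  if (length(alleles_A) > 1L || length(alleles_D) > 1L) return("multi_allele")
  if (TRANSITION_PARTNER[[alleles_A]] == alleles_D) "transition" else "transversion"
}

qualifying_alleles <- function(counts, maf_threshold, fixation_threshold) {
  counts <- counts[BASES]
  counts[is.na(counts)] <- 0
  tot <- sum(counts)
  if (tot == 0) return(character())
  freq <- counts / tot
  if (max(freq) >= fixation_threshold) {
    return(names(which.max(freq)))
  }
  names(freq)[freq >= maf_threshold]
}

as_base_counts <- function(col) {
  if (is.list(col) && !is.null(col$base_counts)) col$base_counts else col
}

#' Call one reference position from the two diploid pileup columns
#'
#' Each genome's qualifying allele set holds the bases at frequency at
#' least `maf_threshold`; a genome whose major allele reaches
#' `fixation_threshold` is treated as fixed for that single base. A site
#' is a homoeo-SNP when the two qualifying sets are non-empty and
#' disjoint. A base qualifying in both genomes is removed from the
#' genome(s) where it is not the major allele, and that genome receives
#' a within-genome allele-SNP annotation; if the sets still intersect
#' the site cannot be indexed.
#'
#' @param col_A,col_D Pileup columns (from [parse_mpileup_line()]) or
#'   bare named A/C/G/T count vectors for the A- and D-genome diploid.
#' @param min_coverage Minimum per-genome base count (default 4).
#' @param maf_threshold Minor allele frequency floor (default 0.40).
#' @param fixation_threshold Major-allele frequency at which a genome is
#'   considered fixed (default 0.90).
#' @return List with `verdict` (homoeo_snp / allele_snp_A /
#'   allele_snp_D / no_call), `alleles_A`, `alleles_D`, `snp_type`, and
#'   `allele_snp` (genomes with a within-genome polymorphism noted).
#' @export
call_site <- function(col_A, col_D, min_coverage = 4L, maf_threshold = 0.4,
                      fixation_threshold = 0.9) {
  if (is.list(col_A) && is.list(col_D) &&
      !is.null(col_A$pos) && !is.null(col_D$pos)) {
    if (!identical(col_A$chrom, col_D$chrom) || col_A$pos != col_D$pos) {
      stop("call_site: pileup columns refer to different positions")
    }
  }
  cA <- as_base_counts(col_A)
  cD <- as_base_counts(col_D)
  cA <- cA[BASES]; cA[is.na(cA)] <- 0; names(cA) <- BASES
  cD <- cD[BASES]; cD[is.na(cD)] <- 0; names(cD) <- BASES
  no_call <- list(verdict = "no_call", alleles_A = character(),
                  alleles_D = character(), snp_type = NA_character_,
                  allele_snp = character())
  if (sum(cA) < min_coverage || sum(cD) < min_coverage) return(no_call)
  qA <- qualifying_alleles(cA, maf_threshold, fixation_threshold)
  qD <- qualifying_alleles(cD, maf_threshold, fixation_threshold)
  if (length(qA) == 0L || length(qD) == 0L) return(no_call)
  allele_snp <- character()
  if (length(qA) > 1L) allele_snp <- c(allele_snp, "A")
  if (length(qD) > 1L) allele_snp <- c(allele_snp, "D")
  shared <- intersect(qA, qD)
  rA <- qA
  rD <- qD
  for (b in shared) {
    major_A <- b == names(which.max(cA))
    major_D <- b == names(which.max(cD))
    # the genome where the shared base is not the major allele loses it
    if (major_A && !major_D) {
      rD <- setdiff(rD, b)
    } else if (major_D && !major_A) {
      rA <- setdiff(rA, b)
    } else {
      rA <- setdiff(rA, b)
      rD <- setdiff(rD, b)
    }
  }
  if (length(rA) > 0L && length(rD) > 0L &&
      length(intersect(rA, rD)) == 0L) {
    return(list(verdict = "homoeo_snp", alleles_A = sort(rA),
                alleles_D = sort(rD), snp_type = classify_snp(rA, rD),
                allele_snp = allele_snp))
  }
  if ("A" %in% allele_snp) {
    return(list(verdict = "allele_snp_A", alleles_A = sort(qA),
                alleles_D = character(), snp_type = NA_character_,
                allele_snp = allele_snp))
  }
  if ("D" %in% allele_snp) {
    return(list(verdict = "allele_snp_D", alleles_A = character(),
                alleles_D = sort(qD), snp_type = NA_character_,
                allele_snp = allele_snp))
  }
  no_call
}

check_sorted <- function(dt, label) {
  if (nrow(dt) < 2L) return(invisible())
  o <- order(dt$chrom, dt$pos)
  if (!identical(o, seq_len(nrow(dt)))) {
    # find the first record out of order relative to its predecessor
    same <- dt$chrom[-1L] == dt$chrom[-nrow(dt)]
    bad <- which(same & dt$pos[-1L] <= dt$pos[-nrow(dt)])
    w <- if (length(bad)) bad[1L] + 1L else which(o != seq_len(nrow(dt)))[1L]
    hs_data_error("%s pileup not position-sorted at %s:%d", label,
                  dt$chrom[w], dt$pos[w] + 1L)
  }
  invisible()
}

#' Build a homoeo-SNP index from two diploid pileups
#'
#' Performs a coordinated merge-walk over the two position-sorted pileup
#' streams; positions present in only one stream cannot be called.
#' Homoeo-SNP verdicts become index records; within-genome allele-SNP
#' verdicts are collected in a side table.
#'
#' @param pileup_A,pileup_D Paths to mpileup files, character vectors of
#'   lines, or tables from [read_mpileup()], for the A- and D-genome
#'   diploid respectively. Both must be sorted by chromosome and
#'   position on the same reference.
#' @param reference Reference name stored in index metadata.
#' @inheritParams call_site
#' @return List with `index` (a [snp_index()]) and `allele_snps` (side
#'   table of within-genome polymorphisms).
#' @export
build_index <- function(pileup_A, pileup_D, reference = "unknown",
                        min_coverage = 4L, maf_threshold = 0.4,
                        fixation_threshold = 0.9) {
  pA <- if (is.data.frame(pileup_A)) as.data.table(pileup_A) else read_mpileup(pileup_A)
  pD <- if (is.data.frame(pileup_D)) as.data.table(pileup_D) else read_mpileup(pileup_D)
  check_sorted(pA, "A-genome")
  check_sorted(pD, "D-genome")
  empty <- build_result_empty(reference, min_coverage, maf_threshold,
                              fixation_threshold)
  if (nrow(pA) == 0L || nrow(pD) == 0L) return(empty)
  m <- merge(pA, pD, by = c("chrom", "pos"), suffixes = c(".A", ".D"))
  if (nrow(m) == 0L) return(empty)
  setorder(m, chrom, pos)
  totA <- m$nA.A + m$nC.A + m$nG.A + m$nT.A
  totD <- m$nA.D + m$nC.D + m$nG.D + m$nT.D
  m <- m[totA >= min_coverage & totD >= min_coverage]
  if (nrow(m) == 0L) return(empty)
  CA <- as.matrix(m[, .(nA.A, nC.A, nG.A, nT.A)])
  CD <- as.matrix(m[, .(nA.D, nC.D, nG.D, nT.D)])
  colnames(CA) <- colnames(CD) <- BASES
  fA <- CA / rowSums(CA)
  fD <- CD / rowSums(CD)
  majA <- BASES[max.col(fA, ties.method = "first")]
  majD <- BASES[max.col(fD, ties.method = "first")]
  fixedA <- apply(fA, 1L, max) >= fixation_threshold
  fixedD <- apply(fD, 1L, max) >= fixation_threshold
  # fast path: both genomes fixed for a single (different) base
  fast <- fixedA & fixedD
  rec_list <- list()
  if (any(fast & majA != majD)) {
    i <- which(fast & majA != majD)
    rec_list[[1L]] <- data.table(
      chrom = m$chrom[i], pos = m$pos[i], ref_base = m$ref_base.D[i],
      alleles_A = majA[i], alleles_D = majD[i],
      snp_type = ifelse(TRANSITION_PARTNER[majA[i]] == majD[i],
                        "transition", "transversion"),
      origin = "diploid_pileup")
  }
  side_list <- list()
  slow <- which(!fast)
  if (length(slow)) {
    srec <- vector("list", length(slow))
    sside <- vector("list", length(slow))
    for (j in seq_along(slow)) {
      i <- slow[j]
      call <- call_site(CA[i, ], CD[i, ], min_coverage, maf_threshold,
                        fixation_threshold)
      if (call$verdict == "homoeo_snp") {
        srec[[j]] <- data.table(
          chrom = m$chrom[i], pos = m$pos[i], ref_base = m$ref_base.D[i],
          alleles_A = allele_join(call$alleles_A),
          alleles_D = allele_join(call$alleles_D),
          snp_type = call$snp_type, origin = "diploid_pileup")
      }
      if (length(call$allele_snp) || startsWith(call$verdict, "allele_snp")) {
        genomes <- unique(c(call$allele_snp,
                            sub("allele_snp_", "",
                                grep("^allele_snp", call$verdict, value = TRUE))))
        sside[[j]] <- data.table(chrom = m$chrom[i], pos = m$pos[i],
                                 genome = genomes)
      }
    }
    rec_list <- c(rec_list, srec[!vapply(srec, is.null, TRUE)])
    side_list <- sside[!vapply(sside, is.null, TRUE)]
  }
  records <- if (length(rec_list)) rbindlist(rec_list) else NULL
  side <- if (length(side_list)) rbindlist(side_list) else
    data.table(chrom = character(), pos = integer(), genome = character())
  setorder(side, chrom, pos)
  list(index = snp_index(records, reference, min_coverage, maf_threshold,
                         fixation_threshold),
       allele_snps = side)
}

build_result_empty <- function(reference, min_coverage, maf_threshold,
                               fixation_threshold) {
  list(index = snp_index(NULL, reference, min_coverage, maf_threshold,
                         fixation_threshold),
       allele_snps = data.table(chrom = character(), pos = integer(),
                                genome = character()))
}

#' Summarize an index by allele-pair composition
#'
#' Tabulates single-allele records into the 12 ordered (A-genome allele,
#' D-genome allele) cells, sums transitions (A-G and C-T cells) and
#' transversions (the remaining 8 cells), and reports the
#' transition/transversion ratio and the transition share of the whole
#' index (multi-allele records included in the total but unclassified).
#'
#' @param index A [snp_index()].
#' @return See [snp_pair_summary()].
#' @export
index_summary <- function(index) {
  single <- !grepl(",", index$alleles_A, fixed = TRUE) &
    !grepl(",", index$alleles_D, fixed = TRUE)
  pair_counts <- matrix(0, 4L, 4L, dimnames = list(BASES, BASES))
  if (any(single)) {
    tab <- table(factor(index$alleles_A[single], levels = BASES),
                 factor(index$alleles_D[single], levels = BASES))
    pair_counts <- pair_counts + unclass(tab)
  }
  snp_pair_summary(pair_counts, n_multi = sum(!single))
}

#' Summarize homoeo-SNP composition from allele-pair counts
#'
#' The count-level core of [index_summary()], usable directly on a
#' published composition table.
#'
#' @param pair_counts 4x4 matrix of counts, rows = A-genome allele,
#'   columns = D-genome allele (A, C, G, T); the diagonal must be zero.
#' @param n_multi Number of records with more than one allele in either
#'   genome (unclassifiable as transition/transversion).
#' @return List with `pair_counts`, `transitions`, `transversions`,
#'   `multi_allele`, `total`, `titv_ratio` and `transition_share_pct`.
#' @export
snp_pair_summary <- function(pair_counts, n_multi = 0L) {
  pair_counts <- pair_counts[BASES, BASES]
  if (any(diag(pair_counts) != 0)) {
    hs_data_error("diagonal of an allele-pair table must be zero")
  }
  is_transition <- matrix(FALSE, 4L, 4L, dimnames = list(BASES, BASES))
  for (b in BASES) is_transition[b, TRANSITION_PARTNER[[b]]] <- TRUE
  transitions <- sum(pair_counts[is_transition])
  transversions <- sum(pair_counts) - transitions
  total <- transitions + transversions + n_multi
  list(pair_counts = pair_counts,
       transitions = transitions,
       transversions = transversions,
       multi_allele = n_multi,
       total = total,
       titv_ratio = if (transversions > 0) transitions / transversions else NaN,
       transition_share_pct = if (total > 0) 100 * transitions / total else NaN)
}

#' Merge a new index into an existing one
#'
#' Records at new positions are appended. At positions present in both,
#' allele sets are unioned per genome; if the unioned sets intersect the
#' position can no longer discriminate the genomes and is dropped (its
#' bases are effectively masked), with a message reporting the count.
#'
#' @param base,additions Two [snp_index()] objects on the same reference.
#' @return Merged [snp_index()].
#' @export
merge_indexes <- function(base, additions) {
  md_b <- attr(base, "metadata")
  md_a <- attr(additions, "metadata")
  if (!identical(md_b$reference, md_a$reference)) {
    hs_data_error("cannot merge indexes on different references ('%s' vs '%s')",
                  md_b$reference, md_a$reference)
  }
  b <- as.data.table(base)
  a <- as.data.table(additions)
  both <- merge(b, a, by = c("chrom", "pos"), suffixes = c(".b", ".a"))
  only_b <- b[!a, on = c("chrom", "pos")]
  only_a <- a[!b, on = c("chrom", "pos")]
  merged <- NULL
  n_dropped <- 0L
  if (nrow(both)) {
    uA <- mapply(function(x, y) allele_join(union(x, y)),
                 allele_split(both$alleles_A.b), allele_split(both$alleles_A.a))
    uD <- mapply(function(x, y) allele_join(union(x, y)),
                 allele_split(both$alleles_D.b), allele_split(both$alleles_D.a))
    ok <- mapply(function(x, y) length(intersect(x, y)) == 0L,
                 allele_split(uA), allele_split(uD))
    n_dropped <- sum(!ok)
    if (any(ok)) {
      changed <- uA[ok] != both$alleles_A.b[ok] | uD[ok] != both$alleles_D.b[ok]
      merged <- data.table(
        chrom = both$chrom[ok], pos = both$pos[ok],
        ref_base = both$ref_base.b[ok],
        alleles_A = uA[ok], alleles_D = uD[ok],
        snp_type = mapply(classify_snp, allele_split(uA[ok]),
                          allele_split(uD[ok])),
        origin = ifelse(changed, "merged", both$origin.b[ok]))
    }
  }
  if (n_dropped > 0L) {
    message(sprintf("merge_indexes: dropped %d position(s) whose unioned allele sets intersect",
                    n_dropped))
  }
  out <- rbindlist(c(list(only_b, only_a), if (!is.null(merged)) list(merged)),
                   use.names = TRUE)
  snp_index(out, md_b$reference, md_b$min_coverage, md_b$maf_threshold,
            md_b$fixation_threshold)
}

#' Write / read the tab-delimited index format
#'
#' Header lines carry the reference name and build parameters; data
#' columns are chrom, 1-based position, reference base, comma-joined
#' allele sets for each genome, SNP type, and provenance. Reading
#' enforces the index invariants (unique positions, disjoint allele
#' sets).
#'
#' @param index A [snp_index()].
#' @param path File path.
#' @return `write_index` the path, invisibly; `read_index` a
#'   [snp_index()].
#' @export
write_index <- function(index, path) {
  md <- attr(index, "metadata")
  hdr <- c(sprintf("#reference=%s", md$reference),
           sprintf("#min_coverage=%d", md$min_coverage),
           sprintf("#maf_threshold=%g", md$maf_threshold),
           sprintf("#fixation_threshold=%g", md$fixation_threshold),
           "#chrom\tpos\tref_base\talleles_A\talleles_D\tsnp_type\torigin")
  body <- if (nrow(index) == 0L) character() else
    index[, paste(chrom, pos + 1L, ref_base, alleles_A, alleles_D, snp_type,
                  origin, sep = "\t")]
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  if (!file.exists(path)) hs_data_error("index file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  meta <- list(reference = "unknown", min_coverage = 4L, maf_threshold = 0.4,
               fixation_threshold = 0.9)
  kv <- sub("^#", "", hdr[grepl("=", hdr, fixed = TRUE)])
  for (item in strsplit(kv, "=", fixed = TRUE)) {
    if (item[1L] == "reference") meta$reference <- item[2L]
    if (item[1L] == "min_coverage") meta$min_coverage <- as.integer(item[2L])
    if (item[1L] == "maf_threshold") meta$maf_threshold <- as.numeric(item[2L])
    if (item[1L] == "fixation_threshold") meta$fixation_threshold <- as.numeric(item[2L])
  }
  if (length(body) == 0L) {
    return(snp_index(NULL, meta$reference, meta$min_coverage,
                     meta$maf_threshold, meta$fixation_threshold))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L)) {
    w <- which(nf < 6L)[1L]
    hs_data_error("malformed index line %d: expected >= 6 fields, got %d",
                  which(!startsWith(lines, "#"))[w], nf[w])
  }
  records <- data.table(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)) - 1L,
    ref_base = vapply(parts, `[`, "", 3L),
    alleles_A = vapply(parts, `[`, "", 4L),
    alleles_D = vapply(parts, `[`, "", 5L),
    snp_type = vapply(parts, `[`, "", 6L),
    origin = vapply(parts, function(p)
      if (length(p) >= 7L) p[7L] else "diploid_pileup", ""))
  if (anyNA(records$pos)) {
    hs_data_error("malformed index line: non-numeric position")
  }
  snp_index(records, meta$reference, meta$min_coverage, meta$maf_threshold,
            meta$fixation_threshold)
}

#' Export an index for a SNP-tolerant mapper
#'
#' One line per SNP in the dialect `>label chrom:pos1 XY` where XY is a
#' two-character allele string, reference-matching allele first.
#' Multi-allele records expand to one line per non-reference allele;
#' records where neither allele equals the reference expand to one line
#' per alternate, each paired with the reference base. Labels are "s"
#' plus a running ordinal in sort order.
#'
#' @param index A [snp_index()].
#' @param path Output path.
#' @return Number of lines written, invisibly.
#' @export
export_gsnap <- function(index, path) {
  lines <- character()
  n_nonref <- 0L
  if (nrow(index)) {
    per_record <- vector("list", nrow(index))
    aA <- allele_split(index$alleles_A)
    aD <- allele_split(index$alleles_D)
    for (i in seq_len(nrow(index))) {
      alleles <- c(aA[[i]], aD[[i]])
      ref <- index$ref_base[i]
      alts <- setdiff(alleles, ref)
      if (length(alts) == length(alleles)) n_nonref <- n_nonref + 1L
      per_record[[i]] <- sprintf("%s:%d %s%s", index$chrom[i],
                                 index$pos[i] + 1L, ref, alts)
    }
    flat <- unlist(per_record, use.names = FALSE)
    lines <- sprintf(">s%d %s", seq_along(flat), flat)
  }
  writeLines(lines, path)
  if (n_nonref > 0L) {
    message(sprintf("export_gsnap: %d record(s) had no reference-matching allele; exported as reference-vs-alternate pairs",
                    n_nonref))
  }
  invisible(length(lines))
}

#' Export an index as a minimal VCF (write-only convenience)
#'
#' ALT holds the non-reference alleles; INFO tags GA/GD carry each
#' genome's allele set.
#'
#' @param index A [snp_index()].
#' @param path Output path.
#' @export
export_vcf <- function(index, path) {
  md <- attr(index, "metadata")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##reference=%s", md$reference),
           "##INFO=<ID=GA,Number=.,Type=String,Description=\"A-genome alleles\">",
           "##INFO=<ID=GD,Number=.,Type=String,Description=\"D-genome alleles\">",
           "##INFO=<ID=ST,Number=1,Type=String,Description=\"SNP type\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character()
  if (nrow(index)) {
    alts <- mapply(function(a, d, r) {
      x <- setdiff(union(a, d), r)
      if (length(x) == 0L) "." else paste(x, collapse = ",")
    }, allele_split(index$alleles_A), allele_split(index$alleles_D),
    index$ref_base)
    body <- index[, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tGA=%s;GD=%s;ST=%s",
                            chrom, pos + 1L, ref_base, alts, alleles_A,
                            alleles_D, snp_type)]
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
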