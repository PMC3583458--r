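# Read categorization: compare each aligned read's bases at indexed
# homoeo-SNP positions against the per-genome allele sets and assign the
# read to A, D, X (chimeric) or N (unknown).

#' Categorizer configuration
#'
#' @param threshold Fraction of genome-informative matches required to
#'   call a single genome; must exceed 0.5 so at most one genome can
#'   reach it. Inclusive (a read at exactly the threshold is called).
#' @param min_base_quality Phred floor below which a base at an indexed
#'   site is skipped as uninformative.
#' @param pair_mode "joint" sums mate tallies before categorizing (both
#'   mates receive the joint category); "independent" categorizes each
#'   mate alone.
#' @param tag_category,tag_a,tag_d SAM auxiliary tag names used to
#'   record the category and the per-genome match tallies.
#' @return List of class `categorizer_config`.
#' @export
categorizer_config <- function(threshold = 0.75, min_base_quality = 20L,
                               pair_mode = c("joint", "independent"),
                               tag_category = "YC", tag_a = "YA",
                               tag_d = "YD") {
  pair_mode <- match.arg(pair_mode)
  if (!(threshold > 0.5 && threshold <= 1)) {
    hs_usage_error("threshold must lie in (0.5, 1], got %g", threshold)
  }
  structure(list(threshold = threshold,
                 min_base_quality = as.integer(min_base_quality),
                 pair_mode = pair_mode, tag_category = tag_category,
                 tag_a = tag_a, tag_d = tag_d),
            class = "categorizer_config")
}

# split comma-joined allele columns once per index for fast membership tests
index_lookup <- function(index) {
  lk <- as.data.table(index)[, .(chrom, pos, alleles_A, alleles_D)]
  lk[, `:=`(listA = allele_split(alleles_A), listD = allele_split(alleles_D))]
  setkey(lk, chrom, pos)
  lk
}

#' Inspect one read's bases at every overlapped indexed site
#'
#' For each alignment column of the read that lands on an indexed
#' position, the read base is compared with the two genomes' allele
#' sets. Bases below the quality floor, and N bases, are skipped as
#' uninformative; indexed positions falling inside deletions or
#' reference skips of this read are absent from the result.
#'
#' @param read A single-row list/data.table with fields rname, pos
#'   (1-based), cigar, seq, qual.
#' @param index A [snp_index()] or a prebuilt [index_lookup()] table.
#' @param config A [categorizer_config()].
#' @return data.table with columns pos (0-based), read_base, base_qual,
#'   verdict (matches_A / matches_D / matches_neither /
#'   uninformative_skipped).
#' @export
genotype_read <- function(read, index, config = categorizer_config()) {
  lk <- if (is.data.table(index) && "listA" %in% names(index)) index
        else index_lookup(index)
  empty <- data.table(pos = integer(), read_base = character(),
                      base_qual = integer(), verdict = character())
  pairs <- read_to_reference_pairs(read$pos, read$cigar)
  if (nrow(pairs) == 0L) return(empty)
  jj <- lk[.(rep(read$rname, nrow(pairs)), pairs$ref_pos), which = TRUE]
  keep <- !is.na(jj)
  if (!any(keep)) return(empty)
  rows <- lk[jj[keep]]
  offs <- pairs$read_offset[keep]
  poss <- pairs$ref_pos[keep]
  bases <- toupper(substring(read$seq, offs + 1L, offs + 1L))
  quals <- if (identical(read$qual, "*")) rep(Inf, length(offs)) else
    phred_quals(read$qual)[offs + 1L]
  verdict <- character(length(poss))
  for (i in seq_along(poss)) {
    b <- bases[i]
    if (is.na(quals[i]) || quals[i] < config$min_base_quality || b == "N") {
      verdict[i] <- "uninformative_skipped"
    } else if (b %in% rows$listA[[i]]) {
      verdict[i] <- "matches_A"
    } else if (b %in% rows$listD[[i]]) {
      verdict[i] <- "matches_D"
    } else {
      verdict[i] <- "matches_neither"
    }
  }
  data.table(pos = poss, read_base = bases, base_qual = quals,
             verdict = verdict)
}

#' Turn site-match verdicts into a genome category
#'
#' With a = A-genome matches and d = D-genome matches: no matches at all
#' gives N (unknown); a genome whose share a/(a+d) reaches the threshold
#' (inclusive) gives A or D; otherwise the read matched both genomes and
#' is X (chimeric). Mismatched bases (`matches_neither`) and
#' quality-skipped sites count toward the overlap tally only — they are
#' sequencing noise, not genome evidence.
#'
#' @param matches data.table from [genotype_read()], or a list with
#'   precomputed `a` and `d` tallies.
#' @param config A [categorizer_config()].
#' @return List with category (A/D/X/N), n_matches_A, n_matches_D,
#'   n_neither, n_sites_overlapped.
#' @export
categorize <- function(matches, config = categorizer_config()) {
  if (is.data.frame(matches)) {
    a <- sum(matches$verdict == "matches_A")
    d <- sum(matches$verdict == "matches_D")
    neither <- sum(matches$verdict == "matches_neither")
    n_sites <- nrow(matches)
  } else {
    a <- matches$a
    d <- matches$d
    neither <- if (is.null(matches$neither)) 0L else matches$neither
    n_sites <- if (is.null(matches$n_sites)) a + d + neither else matches$n_sites
  }
  category <- if (a + d == 0L) {
    "N"
  } else if (a / (a + d) >= config$threshold) {
    "A"
  } else if (d / (a + d) >= config$threshold) {
    "D"
  } else {
    "X"
  }
  list(category = category, n_matches_A = a, n_matches_D = d,
       n_neither = neither, n_sites_overlapped = n_sites)
}

FLAG_PAIRED <- 1L
FLAG_UNMAPPED <- 4L
FLAG_SECONDARY <- 256L
FLAG_SUPPLEMENTARY <- 2048L

#' Partition an alignment file by genome of origin
#'
#' Every mapped primary read is categorized and routed to one of four
#' outputs (.A, .D, .X, .N); unmapped reads go to .N and secondary or
#' supplementary records are skipped (counted in the statistics). Each
#' emitted record carries the category and the a/d tallies as auxiliary
#' tags. In joint pair mode, mate tallies are summed before the category
#' decision and both mates receive the joint category; a mate whose
#' partner is unmapped is categorized alone.
#'
#' @param alignment Path to a SAM/BAM file or a list from
#'   [read_alignments()].
#' @param index A [snp_index()].
#' @param config A [categorizer_config()].
#' @param out_prefix If non-NULL, SAM outputs are written to
#'   `<prefix>.A.sam` etc. (or `<prefix>.tagged.sam` with `tag_only`).
#' @param tag_only Write one tagged output instead of four partitions.
#' @param bs Categorize in bisulfite mode via [evaluate_bs_read()];
#'   requires `reference`.
#' @param reference Named character vector of reference sequences
#'   (bisulfite mode only).
#' @return List with `reads` (input records plus category/a/d columns),
#'   `stats` (category, count, fraction over categorized records) and
#'   `counters` (secondary_skipped, unmapped).
#' @export
partition_alignment <- function(alignment, index,
                                config = categorizer_config(),
                                out_prefix = NULL, tag_only = FALSE,
                                bs = FALSE, reference = NULL) {
  aln <- if (is.character(alignment)) read_alignments(alignment) else alignment
  reads <- copy(aln$reads)
  lk <- index_lookup(index)
  if (bs && is.null(reference)) {
    hs_usage_error("bisulfite categorization requires a reference")
  }
  n <- nrow(reads)
  category <- character(n)
  a_tal <- integer(n)
  d_tal <- integer(n)
  secondary <- bitwAnd(reads$flag, FLAG_SECONDARY + FLAG_SUPPLEMENTARY) != 0L
  unmapped <- bitwAnd(reads$flag, FLAG_UNMAPPED) != 0L
  rn <- reads$rname; ps <- reads$pos; cg <- reads$cigar
  sq <- reads$seq; ql <- reads$qual
  for (i in seq_len(n)) {
    if (secondary[i]) next
    if (unmapped[i]) {
      category[i] <- "N"
      next
    }
    row <- list(rname = rn[i], pos = ps[i], cigar = cg[i], seq = sq[i],
                qual = ql[i])
    res <- if (bs) {
      evaluate_bs_read(row, lk, reference, config)
    } else {
      categorize(genotype_read(row, lk, config), config)
    }
    category[i] <- res$category
    a_tal[i] <- res$n_matches_A
    d_tal[i] <- res$n_matches_D
  }
  if (config$pair_mode == "joint") {
    paired <- bitwAnd(reads$flag, FLAG_PAIRED) != 0L
    eligible <- paired & !secondary & !unmapped
    if (any(eligible)) {
      grp <- split(which(eligible), reads$qname[which(eligible)])
      for (idx in grp) {
        if (length(idx) < 2L) next   # mate unmapped or absent: stands alone
        a <- sum(a_tal[idx])
        d <- sum(d_tal[idx])
        joint <- categorize(list(a = a, d = d), config)$category
        category[idx] <- joint
      }
    }
  }
  reads[, `:=`(category = category, a = a_tal, d = d_tal)]
  cat_reads <- reads[!secondary]
  stats <- cat_reads[, .N, by = category][
    data.table(category = c("A", "D", "X", "N")), on = "category"]
  stats[is.na(N), N := 0L]
  stats[, fraction := if (sum(N) > 0) N / sum(N) else 0]
  setnames(stats, "N", "count")
  if (!is.null(out_prefix)) {
    tagged <- copy(reads[!secondary])
    extra <- sprintf("%s:Z:%s\t%s:i:%d\t%s:i:%d", config$tag_category,
                     tagged$category, config$tag_a, tagged$a,
                     config$tag_d, tagged$d)
    tagged[, tags := ifelse(nzchar(tags), paste(tags, extra, sep = "\t"),
                            extra)]
    if (tag_only) {
      write_alignments(list(header = aln$header, reads = tagged),
                       paste0(out_prefix, ".tagged.sam"))
    } else {
      for (cc in c("A", "D", "X", "N")) {
        write_alignments(list(header = aln$header,
                              reads = tagged[category == cc]),
                         paste0(out_prefix, ".", cc, ".sam"))
      }
    }
    utils::write.table(stats, paste0(out_prefix, ".stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(reads = reads, stats = stats,
       counters = list(secondary_skipped = sum(secondary),
                       unmapped = sum(unmapped & !secondary)))
}
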