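# Bisulfite-aware categorization and methylation reporting.
#
# Bisulfite treatment deaminates unmethylated cytosines; after PCR and
# sequencing this reads out as C->T mismatches on plus-strand reads and
# G->A mismatches on minus-strand reads. Conversion is therefore
# confounded with transition homoeo-SNPs: a C/T SNP cannot be scored on
# a plus-strand read (the T could be an unmethylated C), but is fully
# informative on a minus-strand read, and symmetrically for G/A SNPs.

#' Infer the origin strand of a bisulfite read
#'
#' Counts reference-C/read-T (n_ct) and reference-G/read-A (n_ga)
#' mismatch columns over the aligned pairs. More C->T conversions mean
#' the read derives from the plus strand, more G->A the minus strand;
#' equal counts (including 0/0) are ambiguous and later weighted as half
#' a read on each strand. Indexed homoeo-SNP positions are excluded from
#' the counts so a C/T SNP does not masquerade as conversion.
#'
#' @param read Single-row list with rname, pos, cigar, seq.
#' @param reference Named character vector of reference sequences.
#' @param index Optional [snp_index()] (or lookup) whose positions are
#'   excluded from conversion counting.
#' @return List with `strand` (plus/minus/ambiguous), `n_ct`, `n_ga`.
#' @export
infer_strand <- function(read, reference, index = NULL) {
  pairs <- read_to_reference_pairs(read$pos, read$cigar)
  if (nrow(pairs) == 0L) return(list(strand = "ambiguous", n_ct = 0L, n_ga = 0L))
  refseq <- reference[[read$rname]]
  if (is.null(refseq)) {
    hs_data_error("chromosome '%s' absent from reference", read$rname)
  }
  if (!is.null(index)) {
    lk <- if (is.data.table(index) && "listA" %in% names(index)) index
          else index_lookup(index)
    jj <- lk[.(rep(read$rname, nrow(pairs)), pairs$ref_pos), which = TRUE]
    pairs <- pairs[is.na(jj)]
  }
  if (nrow(pairs) == 0L) return(list(strand = "ambiguous", n_ct = 0L, n_ga = 0L))
  rb <- substring(refseq, pairs$ref_pos + 1L, pairs$ref_pos + 1L)
  qb <- substring(read$seq, pairs$read_offset + 1L, pairs$read_offset + 1L)
  n_ct <- sum(rb == "C" & qb == "T")
  n_ga <- sum(rb == "G" & qb == "A")
  strand <- if (n_ct > n_ga) "plus" else if (n_ga > n_ct) "minus" else "ambiguous"
  list(strand = strand, n_ct = n_ct, n_ga = n_ga)
}

#' Strand-aware, conversion-tolerant allele matching at one site
#'
#' A site whose allele sets place a C (one genome) against a T (the
#' other) is uninformative on plus-strand reads, and a G-vs-A site on
#' minus-strand reads: conversion makes the two genomes
#' indistinguishable there. At informative sites, matching tolerates
#' conversion — a read T matches a C allele on the plus strand, a read
#' A matches a G allele on the minus strand — in addition to exact base
#' equality.
#'
#' @param read_base Observed read base.
#' @param alleles_A,alleles_D Allele sets (character vectors or
#'   comma-joined strings).
#' @param strand "plus" or "minus".
#' @return One of matches_A, matches_D, matches_neither,
#'   uninformative_strand.
#' @export
bs_match <- function(read_base, alleles_A, alleles_D, strand) {
  if (length(alleles_A) == 1L && grepl(",", alleles_A, fixed = TRUE))
    alleles_A <- allele_split(alleles_A)[[1L]]
  if (length(alleles_D) == 1L && grepl(",", alleles_D, fixed = TRUE))
    alleles_D <- allele_split(alleles_D)[[1L]]
  stopifnot(strand %in% c("plus", "minus"))
  confounded <- if (strand == "plus") c("C", "T") else c("G", "A")
  # set-wise: any cross-genome allele pair equal to the confounded pair
  if ((confounded[1L] %in% alleles_A && confounded[2L] %in% alleles_D) ||
      (confounded[2L] %in% alleles_A && confounded[1L] %in% alleles_D)) {
    return("uninformative_strand")
  }
  tol <- function(alleles) {
    read_base %in% alleles ||
      (strand == "plus" && read_base == "T" && "C" %in% alleles) ||
      (strand == "minus" && read_base == "A" && "G" %in% alleles)
  }
  hit_A <- tol(alleles_A)
  hit_D <- tol(alleles_D)
  if (hit_A && hit_D) return("uninformative_strand")  # defensive; unreachable
  if (hit_A) return("matches_A")
  if (hit_D) return("matches_D")
  "matches_neither"
}

#' Categorize one bisulfite read
#'
#' The strand is inferred first. Plus/minus reads are matched with
#' [bs_match()] at every overlapped indexed site and categorized with
#' the standard threshold machinery. For ambiguous-strand reads each
#' site is evaluated under both strand hypotheses and used only when
#' the two verdicts agree; a site whose interpretation depends on the
#' unknown strand is dropped as uninformative.
#'
#' @param read Single-row list with rname, pos, cigar, seq, qual.
#' @param index A [snp_index()] or [index_lookup()] table.
#' @param reference Named character vector of reference sequences.
#' @param config A [categorizer_config()].
#' @return As [categorize()], plus `strand` and the site verdicts.
#' @export
evaluate_bs_read <- function(read, index, reference,
                             config = categorizer_config()) {
  lk <- if (is.data.table(index) && "listA" %in% names(index)) index
        else index_lookup(index)
  sc <- infer_strand(read, reference, lk)
  sites <- genotype_read(read, lk, config)
  verdict <- character(nrow(sites))
  if (nrow(sites)) {
    jj <- lk[.(rep(read$rname, nrow(sites)), sites$pos), which = TRUE]
    for (i in seq_len(nrow(sites))) {
      if (sites$verdict[i] == "uninformative_skipped") {
        verdict[i] <- "uninformative_skipped"
        next
      }
      aA <- lk$listA[[jj[i]]]
      aD <- lk$listD[[jj[i]]]
      if (sc$strand == "ambiguous") {
        vp <- bs_match(sites$read_base[i], aA, aD, "plus")
        vm <- bs_match(sites$read_base[i], aA, aD, "minus")
        verdict[i] <- if (identical(vp, vm)) vp else "uninformative_strand"
      } else {
        verdict[i] <- bs_match(sites$read_base[i], aA, aD, sc$strand)
      }
    }
  }
  a <- sum(verdict == "matches_A")
  d <- sum(verdict == "matches_D")
  neither <- sum(verdict == "matches_neither")
  res <- categorize(list(a = a, d = d, neither = neither,
                         n_sites = nrow(sites)), config)
  res$strand <- sc$strand
  res$n_ct <- sc$n_ct
  res$n_ga <- sc$n_ga
  res$site_verdicts <- verdict
  res$sites <- sites
  res
}

#' Trinucleotide methylation context of a cytosine position
#'
#' Plus strand (reference C): CG if the next base is G; CHG if the next
#' base is H (A/C/T) and the one after is G; otherwise CHH. Minus
#' strand (reference G): the mirror image using the two upstream bases.
#' Positions too close to the contig end to resolve the context return
#' "NA" unless the available bases already decide it (e.g. C followed by
#' a terminal G is CG).
#'
#' @param seq Chromosome sequence (single string).
#' @param pos 0-based position; the base there must be C (plus) or G
#'   (minus).
#' @param strand "plus" or "minus".
#' @return "CG", "CHG", "CHH" or "NA".
#' @export
methylation_context <- function(seq, pos, strand) {
  n <- nchar(seq)
  base <- substring(seq, pos + 1L, pos + 1L)
  at <- function(p) if (p < 0L || p >= n) NA_character_ else
    substring(seq, p + 1L, p + 1L)
  if (strand == "plus") {
    if (base != "C") stop("methylation_context: base at position is not C")
    b1 <- at(pos + 1L)
    b2 <- at(pos + 2L)
  } else if (strand == "minus") {
    if (base != "G") stop("methylation_context: base at position is not G")
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    b1 <- at(pos - 1L)
    b2 <- at(pos - 2L)
    if (!is.na(b1)) b1 <- comp[[b1]]
    if (!is.na(b2)) b2 <- comp[[b2]]
  } else {
    stop("methylation_context: strand must be 'plus' or 'minus'")
  }
  h <- c("A", "C", "T")
  if (is.na(b1)) return("NA")
  if (b1 == "G") return("CG")
  if (!b1 %in% h) return("NA")          # N neighbour: unresolvable
  if (is.na(b2)) return("NA")
  if (b2 == "G") return("CHG")
  if (b2 %in% h) return("CHH")
  "NA"
}

#' Per-genome methylation report over every covered C/G position
#'
#' For each covered reference cytosine (plus strand) and guanine (minus
#' strand), tallies unconverted (C / G) and converted (T / A) read
#' bases, using only reads whose inferred strand matches the site
#' strand; ambiguous-strand reads contribute half a read to each
#' strand, so counts can be half-integral. Counts are reported in total
#' and split by the read's category (A, D, X, N).
#'
#' @param alignment Path or [read_alignments()] list. Reads may carry a
#'   category tag from [partition_alignment()]; untagged reads are
#'   categorized inline with [evaluate_bs_read()].
#' @param reference Named character vector of reference sequences.
#' @param index A [snp_index()].
#' @param config A [categorizer_config()].
#' @param out Optional output TSV path.
#' @return data.table with chrom, pos (0-based), strand, context, total
#'   and per-category unconverted/converted columns; zero-coverage
#'   positions are omitted.
#' @export
methylation_report <- function(alignment, reference, index,
                               config = categorizer_config(), out = NULL) {
  aln <- if (is.character(alignment)) read_alignments(alignment) else alignment
  reads <- aln$reads
  lk <- index_lookup(index)
  tag_re <- sprintf("%s:Z:([ADXN])", config$tag_category)
  acc <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    row <- lapply(reads, `[`, i)
    if (bitwAnd(row$flag, FLAG_UNMAPPED + FLAG_SECONDARY + FLAG_SUPPLEMENTARY) != 0L) next
    m <- regmatches(row$tags, regexec(tag_re, row$tags))[[1L]]
    if (length(m) == 2L) {
      cat_i <- m[2L]
      strand_i <- infer_strand(row, reference, lk)$strand
    } else {
      ev <- evaluate_bs_read(row, lk, reference, config)
      cat_i <- ev$category
      strand_i <- ev$strand
    }
    pairs <- read_to_reference_pairs(row$pos, row$cigar)
    if (nrow(pairs) == 0L) next
    refseq <- reference[[row$rname]]
    rb <- substring(refseq, pairs$ref_pos + 1L, pairs$ref_pos + 1L)
    qb <- substring(row$seq, pairs$read_offset + 1L, pairs$read_offset + 1L)
    # plus-strand sites live at reference C, minus-strand at reference G
    take <- function(site_strand) {
      if (!strand_i %in% c(site_strand, "ambiguous")) return(NULL)
      w <- if (strand_i == "ambiguous") 0.5 else 1
      if (site_strand == "plus") {
        sel <- rb == "C" & qb %in% c("C", "T")
        if (!any(sel)) return(NULL)
        data.table(chrom = row$rname, pos = pairs$ref_pos[sel],
                   strand = "plus", cat = cat_i,
                   unconv = w * (qb[sel] == "C"), conv = w * (qb[sel] == "T"))
      } else {
        sel <- rb == "G" & qb %in% c("G", "A")
        if (!any(sel)) return(NULL)
        data.table(chrom = row$rname, pos = pairs$ref_pos[sel],
                   strand = "minus", cat = cat_i,
                   unconv = w * (qb[sel] == "G"), conv = w * (qb[sel] == "A"))
      }
    }
    acc[[i]] <- rbindlist(c(list(take("plus")), list(take("minus"))))
  }
  long <- rbindlist(acc[!vapply(acc, is.null, TRUE)])
  if (is.null(long) || nrow(long) == 0L) {
    rep_dt <- empty_meth_report()
  } else {
    rep_dt <- dcast(long[, .(unconv = sum(unconv), conv = sum(conv)),
                         by = .(chrom, pos, strand, cat)],
                    chrom + pos + strand ~ cat,
                    value.var = c("unconv", "conv"), fill = 0)
    for (cc in c("A", "D", "X", "N")) {
      for (side in c("unconv", "conv")) {
        col <- paste0(side, "_", cc)
        if (!col %in% names(rep_dt)) rep_dt[, (col) := 0]
      }
    }
    rep_dt[, total_unconverted := unconv_A + unconv_D + unconv_X + unconv_N]
    rep_dt[, total_converted := conv_A + conv_D + conv_X + conv_N]
    rep_dt[, context := mapply(function(ch, p, s)
      methylation_context(reference[[ch]], p, s), chrom, pos, strand)]
    setcolorder(rep_dt, c("chrom", "pos", "strand", "context",
                          "total_unconverted", "total_converted",
                          "unconv_A", "conv_A", "unconv_D", "conv_D",
                          "unconv_X", "conv_X", "unconv_N", "conv_N"))
    setorder(rep_dt, chrom, pos, strand)
  }
  if (!is.null(out)) write_meth_report(rep_dt, out, config)
  rep_dt[]
}

empty_meth_report <- function() {
  dt <- data.table(chrom = character(), pos = integer(), strand = character(),
                   context = character(), total_unconverted = numeric(),
                   total_converted = numeric())
  for (cc in c("A", "D", "X", "N")) {
    dt[, (paste0("unconv_", cc)) := numeric()]
    dt[, (paste0("conv_", cc)) := numeric()]
  }
  dt
}

write_meth_report <- function(rep_dt, path, config = categorizer_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#homeosort methylation report\tthreshold=%g\tmin_base_quality=%d",
                     config$threshold, config$min_base_quality), con)
  cols <- c("chrom", "pos", "strand", "context", "total_unconverted",
            "total_converted", "unconv_A", "conv_A", "unconv_D", "conv_D",
            "unconv_X", "conv_X", "unconv_N", "conv_N")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(rep_dt)) {
    fmt1 <- function(x) formatC(x, format = "f", digits = 1)
    body <- rep_dt[, paste(chrom, pos + 1L,
                           ifelse(strand == "plus", "+", "-"), context,
                           fmt1(total_unconverted), fmt1(total_converted),
                           fmt1(unconv_A), fmt1(conv_A),
                           fmt1(unconv_D), fmt1(conv_D),
                           fmt1(unconv_X), fmt1(conv_X),
                           fmt1(unconv_N), fmt1(conv_N), sep = "\t")]
    writeLines(body, con)
  }
  invisible(path)
}
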