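# Index-level genomic statistics: SNP density, per-gene counts, and the
# theoretical fraction of the genome from which a read of given length
# would overlap at least one homoeo-SNP (the categorizability ceiling).

#' Whole-chromosome regions for a reference
#' @param genome_lengths Named integer vector of chromosome lengths.
#' @return data.table with region, chrom, start (0-based), end (half-open).
#' @export
chromosome_regions <- function(genome_lengths) {
  data.table(region = names(genome_lengths), chrom = names(genome_lengths),
             start = 0L, end = as.integer(genome_lengths))
}

#' Fixed-width window regions tiling a reference
#' @inheritParams chromosome_regions
#' @param width Window width in bp.
#' @export
tile_windows <- function(genome_lengths, width) {
  rbindlist(lapply(names(genome_lengths), function(ch) {
    len <- genome_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = width)
    ends <- pmin(starts + width, len)
    data.table(region = sprintf("%s:%d-%d", ch, starts + 1L, ends),
               chrom = ch, start = starts, end = ends)
  }))
}

#' SNP density per region
#'
#' Counts index records whose position lies in each half-open interval
#' and reports SNPs per kbp. A genome-wide mean (total SNPs over total
#' length) is attached as the `genome_density` attribute.
#'
#' @param index A [snp_index()].
#' @param regions data.table with region, chrom, start (0-based), end
#'   (half-open), e.g. from [chromosome_regions()] or [tile_windows()].
#' @return data.table with region, chrom, length_bp, n_snps, density.
#' @export
snp_density <- function(index, regions) {
  regions <- as.data.table(regions)
  if (any(regions$end <= regions$start)) {
    hs_usage_error("zero- or negative-length region: %s",
                   regions$region[which(regions$end <= regions$start)[1L]])
  }
  snps <- as.data.table(index)[, .(chrom, pos)]
  counts <- vapply(seq_len(nrow(regions)), function(i) {
    snps[chrom == regions$chrom[i] & pos >= regions$start[i] &
           pos < regions$end[i], .N]
  }, integer(1L))
  out <- data.table(region = regions$region, chrom = regions$chrom,
                    length_bp = regions$end - regions$start,
                    n_snps = counts)
  out[, density := n_snps / (length_bp / 1000)]
  setattr(out, "genome_density",
          sum(out$n_snps) / (sum(out$length_bp) / 1000))
  out[]
}

resolve_gene_parent <- function(ids, parents, feature_id) {
  # walk Parent chains (exon -> mRNA -> gene) up to a few hops
  cur <- feature_id
  for (hop in 1:5) {
    if (cur %in% ids$gene) return(cur)
    nxt <- parents[[cur]]
    if (is.null(nxt) || length(nxt) == 0L) return(NA_character_)
    cur <- nxt[1L]
  }
  NA_character_
}

#' Per-gene homoeo-SNP counts and histogram
#'
#' Counts index records within each annotated gene span and within its
#' exons (exons resolved to genes through their Parent chain, falling
#' back to span overlap). Overlapping genes each count a shared SNP
#' once. Genes with zero SNPs are reported separately.
#'
#' @param index A [snp_index()].
#' @param gff3 Path to a GFF3 annotation with gene (and optionally
#'   exon) features.
#' @param bin_width Histogram bin width (default 10 SNPs).
#' @return List with `genes` (per-gene table), `histogram` and
#'   `zero_snp_genes`.
#' @export
per_gene_snp_counts <- function(index, gff3, bin_width = 10L) {
  gr <- tryCatch(rtracklayer::import(gff3, format = "gff3"),
                 error = function(e)
                   hs_data_error("malformed GFF3 %s: %s", gff3,
                                 conditionMessage(e)))
  types <- as.character(gr$type)
  genes <- gr[types == "gene"]
  if (length(genes) == 0L) hs_data_error("no gene features in %s", gff3)
  gene_ids <- as.character(genes$ID)
  if (anyNA(gene_ids)) gene_ids <- paste0("gene", seq_along(genes))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = index$chrom,
    ranges = IRanges::IRanges(start = index$pos + 1L, width = 1L))
  n_total <- GenomicRanges::countOverlaps(genes, snp_gr)
  exons <- gr[types == "exon"]
  n_exonic <- rep(0L, length(genes))
  if (length(exons)) {
    parents <- stats::setNames(as.list(gr$Parent), as.character(gr$ID))
    ids <- list(gene = gene_ids)
    exon_parent <- vapply(seq_along(exons), function(i) {
      p <- exons$Parent[[i]]
      if (length(p) == 0L) return(NA_character_)
      resolve_gene_parent(ids, parents, as.character(p[1L]))
    }, character(1L))
    if (anyNA(exon_parent)) {
      # fall back: assign orphan exons to the gene span containing them
      orphan <- which(is.na(exon_parent))
      hit <- GenomicRanges::findOverlaps(exons[orphan], genes,
                                         select = "first")
      exon_parent[orphan] <- gene_ids[hit]
    }
    for (g in seq_along(genes)) {
      ex_g <- exons[!is.na(exon_parent) & exon_parent == gene_ids[g]]
      if (length(ex_g) == 0L) next
      n_exonic[g] <- sum(IRanges::overlapsAny(
        snp_gr, GenomicRanges::reduce(ex_g)))
    }
  }
  gene_dt <- data.table(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1L,
    end = GenomicRanges::end(genes),
    length_bp = GenomicRanges::width(genes),
    n_snps = n_total, n_exonic = n_exonic)
  lo <- (gene_dt$n_snps %/% bin_width) * bin_width
  hist_dt <- data.table(bin_lo = lo)[, .N, by = bin_lo][order(bin_lo)]
  setnames(hist_dt, "N", "n_genes")
  hist_dt[, bin_hi := bin_lo + bin_width]
  setcolorder(hist_dt, c("bin_lo", "bin_hi", "n_genes"))
  list(genes = gene_dt[], histogram = hist_dt[],
       zero_snp_genes = gene_dt[n_snps == 0L, gene_id])
}

#' Theoretical categorizability of reads of a given length
#'
#' A read start s (0-based) is covered when some indexed position p
#' satisfies s <= p <= s + read_length - 1, i.e. the read would overlap
#' at least one homoeo-SNP. Covered starts are computed exactly by
#' merging the per-SNP start intervals [p - read_length + 1, p], clipped
#' to chromosome bounds, optionally intersected with a region set.
#'
#' @param index A [snp_index()].
#' @param read_length Read length in bp (>= 1).
#' @param genome_lengths Named vector of chromosome lengths.
#' @param regions Optional data.table (region, chrom, start, end) to
#'   restrict both numerator and denominator (e.g. genic regions).
#' @return List with read_length_bp, covered_bp, genome_bp, fraction.
#' @export
categorizable_fraction <- function(index, read_length, genome_lengths,
                                   regions = NULL) {
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 1L) {
    hs_usage_error("read_length must be >= 1")
  }
  covered <- 0
  genome_bp <- 0
  for (ch in names(genome_lengths)) {
    len <- as.integer(genome_lengths[[ch]])
    pos1 <- index[chrom == ch, pos] + 1L        # 1-based SNP positions
    ir <- if (length(pos1)) {
      IRanges::reduce(IRanges::IRanges(
        start = pmax(1L, pos1 - read_length + 1L), end = pmin(pos1, len)))
    } else IRanges::IRanges()
    if (!is.null(regions)) {
      reg <- as.data.table(regions)[chrom == ch]
      if (nrow(reg) == 0L) next
      reg_ir <- IRanges::reduce(IRanges::IRanges(start = reg$start + 1L,
                                                 end = reg$end))
      genome_bp <- genome_bp + sum(IRanges::width(reg_ir))
      ir <- IRanges::intersect(ir, reg_ir)
    } else {
      genome_bp <- genome_bp + len
    }
    covered <- covered + sum(IRanges::width(ir))
  }
  list(read_length_bp = read_length, covered_bp = covered,
       genome_bp = genome_bp,
       fraction = if (genome_bp > 0) covered / genome_bp else 0)
}
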