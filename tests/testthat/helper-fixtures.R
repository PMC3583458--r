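# Shared fixtures, built in code.

library(data.table)

# a small hand-written index: three records on two chromosomes
toy_index <- function() {
  snp_index(data.table(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(9L, 49L, 4L),
    ref_base = c("A", "C", "G"),
    alleles_A = c("G", "C", "G"),
    alleles_D = c("A", "T", "C"),
    snp_type = c("transition", "transition", "transversion")),
    reference = "toy")
}

# one SAM record as the single-row list genotype_read expects
mk_read <- function(rname, pos, cigar, seq, qual = NULL, flag = 0L,
                    qname = "r1") {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  data.table(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = 60L, cigar = cigar,
             rnext = "*", pnext = 0L, tlen = 0L, seq = seq, qual = qual,
             tags = "")
}

mk_alignment <- function(reads, reference = NULL) {
  hdr <- if (is.null(reference)) "@HD\tVN:1.6\tSO:unsorted" else
    sam_header_for(reference)
  list(header = hdr, reads = rbindlist(reads))
}

# brute-force CIGAR walker, independent of the implementation: walks the
# CIGAR one column at a time with explicit cursors
oracle_pairs <- function(pos1, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  ref <- pos1 - 1L
  rd <- 0L
  out <- list()
  for (tok in ops) {
    n <- as.integer(sub("[A-Z=]$", "", tok))
    op <- sub("^[0-9]+", "", tok)
    for (k in seq_len(n)) {
      if (op %in% c("M", "=", "X")) {
        out[[length(out) + 1L]] <- c(rd, ref)
        rd <- rd + 1L
        ref <- ref + 1L
      } else if (op %in% c("I", "S")) {
        rd <- rd + 1L
      } else if (op %in% c("D", "N")) {
        ref <- ref + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.table(read_offset = integer(), ref_pos = integer()))
  }
  m <- do.call(rbind, out)
  data.table(read_offset = m[, 1L], ref_pos = m[, 2L])
}

# hash the raw index table by "chrom:pos" for the brute-force oracle
oracle_hash <- function(index_dt) {
  h <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(index_dt))) {
    assign(paste0(index_dt$chrom[i], ":", index_dt$pos[i]),
           list(A = strsplit(index_dt$alleles_A[i], ",")[[1L]],
                D = strsplit(index_dt$alleles_D[i], ",")[[1L]]),
           envir = h)
  }
  h
}

# brute-force per-read categorizer: re-walks each read base by base
# against a hashed copy of the index, no shared machinery beyond
# oracle_pairs
oracle_categorize_read <- function(read, index_hash, threshold = 0.75,
                                   min_q = 20L) {
  pairs <- oracle_pairs(read$pos, read$cigar)
  a <- 0L
  d <- 0L
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      hit <- mget(paste0(read$rname, ":", pairs$ref_pos[i]),
                  envir = index_hash, ifnotfound = list(NULL))[[1L]]
      if (is.null(hit)) next
      b <- substring(read$seq, pairs$read_offset[i] + 1L,
                     pairs$read_offset[i] + 1L)
      q <- utf8ToInt(substring(read$qual, pairs$read_offset[i] + 1L,
                               pairs$read_offset[i] + 1L)) - 33L
      if (q < min_q || b == "N") next
      if (b %in% hit$A) a <- a + 1L
      else if (b %in% hit$D) d <- d + 1L
    }
  }
  if (a + d == 0L) return("N")
  if (a / (a + d) >= threshold) return("A")
  if (d / (a + d) >= threshold) return("D")
  "X"
}
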