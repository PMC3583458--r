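#' @import data.table
NULL

BASES <- c("A", "C", "G", "T")

# condition helpers: usage errors exit 1 at the CLI, data errors exit 2
hs_data_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("hs_data_error", "error")))
}
hs_usage_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("hs_usage_error", "error")))
}

#' Read a FASTA file into a named vector of uppercase sequences
#'
#' Sequence names are the first whitespace-delimited token of each header;
#' the remainder of the header is dropped. Sequences are uppercased on
#' ingest so that downstream base comparisons are case-free.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) hs_data_error("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) hs_data_error("empty FASTA file: %s", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    hs_data_error("malformed FASTA: line %d does not start a record", lineno[1L])
  }
  rec <- cumsum(is_hdr)
  names_full <- sub("^>", "", lines[is_hdr])
  nm <- vapply(strsplit(names_full, "\\s+"), `[`, character(1L), 1L)
  if (anyNA(nm) || any(nm == "")) {
    bad <- which(is_hdr)[which(is.na(nm) | nm == "")[1L]]
    hs_data_error("malformed FASTA header at line %d", lineno[bad])
  }
  if (anyDuplicated(nm)) {
    hs_data_error("duplicate FASTA record name: %s", nm[anyDuplicated(nm)])
  }
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]), paste, character(1L),
                 collapse = "")
  out <- rep("", length(nm))
  names(out) <- nm
  out[as.integer(names(seqs))] <- toupper(seqs)
  empty <- which(!nzchar(out))
  if (length(empty)) {
    hs_data_error("empty sequence for record '%s' (header line %d)",
                  nm[empty[1L]], lineno[which(is_hdr)[empty[1L]]])
  }
  if (grepl("[^ACGTNRYSWKMBDHV]", paste(out, collapse = ""))) {
    hs_data_error("non-nucleotide characters in FASTA %s", path)
  }
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse one line of samtools mpileup 6-column text output
#'
#' Resolves the pileup dialect: '.'/',' count toward the reference base,
#' mismatch letters toward their own base, '^'+mapq prefixes, '$'
#' suffixes and '+n'/'-n' indel substrings are consumed, and '*', '<',
#' '>' (deletion / reference-skip placeholders) are excluded from base
#' counts. N bases are likewise excluded. Only the 6-column dialect is
#' accepted; lines carrying mapping-quality columns are rejected.
#'
#' @param line A single mpileup text line.
#' @return List with `chrom`, `pos` (0-based), `ref_base`, `depth`, and
#'   `base_counts` (named integer vector over A/C/G/T).
#' @export
parse_mpileup_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) != 6L) {
    hs_data_error(
      "mpileup line has %d columns; only the 6-column dialect is accepted",
      length(f))
  }
  pos1 <- suppressWarnings(as.integer(f[2L]))
  depth <- suppressWarnings(as.integer(f[4L]))
  if (is.na(pos1) || is.na(depth)) hs_data_error("malformed mpileup line: %s", line)
  ref <- toupper(f[3L])
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  n_resolved <- 0L
  chars <- strsplit(f[5L], "", fixed = TRUE)[[1L]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L            # skip the mapping-quality character too
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len           # indel bases excluded from counts
    } else if (ch == "." || ch == ",") {
      if (ref %in% BASES) counts[ref] <- counts[ref] + 1L
      n_resolved <- n_resolved + 1L
      i <- i + 1L
    } else {
      up <- toupper(ch)
      if (up %in% BASES) {
        counts[up] <- counts[up] + 1L
        n_resolved <- n_resolved + 1L
      } else if (up %in% c("N", "*", "<", ">")) {
        n_resolved <- n_resolved + 1L
      } else {
        hs_data_error("unrecognized pileup symbol '%s' in line: %s", ch, line)
      }
      i <- i + 1L
    }
  }
  if (n_resolved != depth) {
    hs_data_error("pileup depth %d disagrees with %d resolved bases: %s",
                  depth, n_resolved, line)
  }
  list(chrom = f[1L], pos = pos1 - 1L, ref_base = ref, depth = depth,
       base_counts = counts)
}

#' Read an mpileup text file into a per-position count table
#'
#' Vectorized over lines without indel/read-start/read-end decorations;
#' decorated lines fall back to [parse_mpileup_line()].
#'
#' @param x Path to an mpileup file, or a character vector of lines.
#' @return data.table with columns chrom, pos (0-based), ref_base, depth,
#'   nA, nC, nG, nT.
#' @export
read_mpileup <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.table(chrom = character(), pos = integer(),
                      ref_base = character(), depth = integer(),
                      nA = integer(), nC = integer(), nG = integer(),
                      nT = integer()))
  }
  parts <- tstrsplit(lines, "\t", fixed = TRUE)
  if (length(parts) != 6L) {
    hs_data_error("mpileup input has %d columns; only the 6-column dialect is accepted",
                  length(parts))
  }
  dt <- data.table(chrom = parts[[1L]], pos = as.integer(parts[[2L]]) - 1L,
                   ref_base = toupper(parts[[3L]]),
                   depth = as.integer(parts[[4L]]), bases = parts[[5L]])
  simple <- !grepl("[$^+-]", dt$bases)
  count_char <- function(s, pat) nchar(s) - nchar(gsub(pat, "", s))
  for (b in BASES) {
    set(dt, j = paste0("n", b), value = 0L)
  }
  if (any(simple)) {
    bs <- dt$bases[simple]
    refmatch <- count_char(bs, "[.,]")
    bad <- which(gsub("[.,ACGTNacgtn*<>]", "", bs) != "")
    if (length(bad)) {
      hs_data_error("unrecognized pileup symbol in line: %s",
                    lines[simple][bad[1L]])
    }
    if (any(nchar(bs) != dt$depth[simple])) {
      w <- which(nchar(bs) != dt$depth[simple])[1L]
      hs_data_error("pileup depth disagrees with base string: %s",
                    lines[simple][w])
    }
    for (b in BASES) {
      cnt <- count_char(bs, sprintf("[%s%s]", b, tolower(b)))
      cnt <- cnt + ifelse(dt$ref_base[simple] == b, refmatch, 0L)
      set(dt, i = which(simple), j = paste0("n", b), value = as.integer(cnt))
    }
  }
  if (any(!simple)) {
    for (i in which(!simple)) {
      col <- parse_mpileup_line(lines[i])
      set(dt, i = i, j = c("nA", "nC", "nG", "nT"),
          value = as.list(as.integer(col$base_counts)))
    }
  }
  dt[, bases := NULL]
  dt[]
}

# ---- CIGAR / alignment coordinate machinery -------------------------------

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(list(op = character(), len = integer()))
  }
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar, perl = TRUE)[[1L]]
  toks <- regmatches(cigar, gregexpr("([0-9]+)([MIDNSHP=X])", cigar))[[1L]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    hs_data_error("malformed CIGAR string: %s", cigar)
  }
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

#' Map read offsets to reference positions for an aligned read
#'
#' Emits one (read_offset, ref_pos) pair per alignment match/mismatch
#' column (CIGAR M/=/X). Insertions, deletions, reference skips (spliced
#' alignments) and clips contribute no pairs. Both coordinates are
#' 0-based; `ref_pos` is strictly increasing.
#'
#' @param pos 1-based leftmost reference position of the alignment (SAM
#'   convention), or a list/row with `pos` and `cigar` fields.
#' @param cigar CIGAR string.
#' @return data.table with integer columns `read_offset` and `ref_pos`.
#' @export
read_to_reference_pairs <- function(pos, cigar = NULL) {
  if (is.list(pos)) {
    cigar <- pos$cigar
    pos <- pos$pos
  }
  if (is.na(pos) || pos <= 0L || is.na(cigar) || cigar == "*") {
    return(data.table(read_offset = integer(), ref_pos = integer()))
  }
  cg <- parse_cigar(cigar)
  ref <- as.integer(pos) - 1L
  rd <- 0L
  ro <- vector("list", length(cg$op))
  rp <- vector("list", length(cg$op))
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]
    len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      ro[[k]] <- rd + seq_len(len) - 1L
      rp[[k]] <- ref + seq_len(len) - 1L
      rd <- rd + len
      ref <- ref + len
    } else if (op %in% c("I", "S")) {
      rd <- rd + len
    } else if (op %in% c("D", "N")) {
      ref <- ref + len
    } # H, P consume nothing
  }
  data.table(read_offset = unlist(ro, use.names = FALSE),
             ref_pos = unlist(rp, use.names = FALSE))
}

cigar_query_length <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X")])
}

# ---- SAM ------------------------------------------------------------------

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

#' Read alignments from SAM (text) or BAM
#'
#' SAM is parsed directly; BAM is read through Rsamtools when available.
#' Only the 11 mandatory fields plus the raw optional-tag string are kept.
#'
#' @param path Path to a .sam or .bam file.
#' @return List with `header` (character vector of header lines) and
#'   `reads` (data.table with the mandatory SAM columns and `tags`).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) hs_data_error("alignment file not found: %s", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(read_bam_alignments(path))
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) {
    reads <- data.table(qname = character(), flag = integer(),
                        rname = character(), pos = integer(),
                        mapq = integer(), cigar = character(),
                        rnext = character(), pnext = integer(),
                        tlen = integer(), seq = character(),
                        qual = character(), tags = character())
    return(list(header = hdr, reads = reads))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    hs_data_error("SAM record with fewer than 11 fields at line %d",
                  which(nf < 11L)[1L])
  }
  reads <- data.table(
    qname = vapply(parts, `[`, "", 1L),
    flag  = as.integer(vapply(parts, `[`, "", 2L)),
    rname = vapply(parts, `[`, "", 3L),
    pos   = as.integer(vapply(parts, `[`, "", 4L)),
    mapq  = as.integer(vapply(parts, `[`, "", 5L)),
    cigar = vapply(parts, `[`, "", 6L),
    rnext = vapply(parts, `[`, "", 7L),
    pnext = as.integer(vapply(parts, `[`, "", 8L)),
    tlen  = as.integer(vapply(parts, `[`, "", 9L)),
    seq   = toupper(vapply(parts, `[`, "", 10L)),
    qual  = vapply(parts, `[`, "", 11L),
    tags  = vapply(parts, function(p)
      if (length(p) > 11L) paste(p[-(1:11)], collapse = "\t") else "", "")
  )
  mapped <- !bitwAnd(reads$flag, 4L) & reads$cigar != "*"
  qlen <- vapply(reads$cigar[mapped], cigar_query_length, integer(1L))
  bad <- which(qlen != nchar(reads$seq[mapped]) & reads$seq[mapped] != "*")
  if (length(bad)) {
    hs_data_error("CIGAR length disagrees with sequence length for read %s",
                  reads$qname[mapped][bad[1L]])
  }
  list(header = hdr, reads = reads)
}

read_bam_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    hs_data_error("BAM input requires the Rsamtools package")
  }
  b <- Rsamtools::scanBam(path)[[1L]]
  reads <- data.table(
    qname = b$qname, flag = as.integer(b$flag),
    rname = as.character(b$rname), pos = as.integer(b$pos),
    mapq = as.integer(b$mapq), cigar = as.character(b$cigar),
    rnext = as.character(b$mrnm), pnext = as.integer(b$mpos),
    tlen = as.integer(b$isize), seq = as.character(b$seq),
    qual = as.character(b$qual), tags = "")
  reads[is.na(pos), pos := 0L]
  reads[is.na(cigar), cigar := "*"]
  reads[is.na(rname), rname := "*"]
  hdr <- Rsamtools::scanBamHeader(path)[[1L]]$text
  hdr_lines <- vapply(seq_along(hdr), function(i)
    paste(c(names(hdr)[i], hdr[[i]]), collapse = "\t"), "")
  list(header = hdr_lines, reads = reads)
}

#' Write alignments as SAM text
#' @param aln List with `header` and `reads` as from [read_alignments()].
#' @param path Output path.
#' @export
write_alignments <- function(aln, path) {
  reads <- aln$reads
  body <- if (nrow(reads) == 0L) character() else {
    base <- do.call(paste, c(reads[, SAM_COLS, with = FALSE], sep = "\t"))
    ifelse(nzchar(reads$tags), paste(base, reads$tags, sep = "\t"), base)
  }
  writeLines(c(aln$header, body), path)
  invisible(path)
}

sam_header_for <- function(reference, sort_order = "unsorted") {
  c(sprintf("@HD\tVN:1.6\tSO:%s", sort_order),
    sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
}

phred_quals <- function(qual_string) {
  as.integer(charToRaw(qual_string)) - 33L
}
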