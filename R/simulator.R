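# Seeded simulator of the allopolyploid test bed: a random D genome, an
# A genome diverged from it at a target homoeo-SNP density and
# transition/transversion ratio, pre-aligned reads with truth labels,
# optional bisulfite conversion, and per-genome pileups. The simulator
# is the stated world every recovery test runs against.

TRANSVERSION_PARTNERS <- list(A = c("C", "T"), C = c("A", "G"),
                              G = c("C", "T"), T = c("A", "G"))

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed %% .Machine$integer.max)
  code
}

#' Simulator configuration
#'
#' Defaults describe the system being emulated: homoeo-SNP density of
#' 3.5 per kbp and a transition/transversion ratio of 1.5 (the values
#' observed for the cotton A/D subgenome pair), 100 bp reads (Illumina
#' HiSeq era), and an equal mixture of the two subgenomes as expected
#' from a balanced allotetraploid.
#'
#' @param genome_length Total reference length in bp.
#' @param n_chroms Number of chromosomes (length split evenly).
#' @param snp_density Homoeo-SNPs per kbp.
#' @param trtv_ratio Target transition/transversion ratio (expectation).
#' @param read_length Read length in bp.
#' @param depth Mean sequencing depth.
#' @param error_rate Per-base substitution error probability.
#' @param a_fraction Fraction of reads drawn from the A genome.
#' @param bs NULL, or list(conversion_rate, methylation = c(CG, CHG,
#'   CHH)) enabling bisulfite simulation.
#' @param seed Integer seed; fully determines all output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L, n_chroms = 1L,
                       snp_density = 3.5, trtv_ratio = 1.5,
                       read_length = 100L, depth = 20, error_rate = 0.001,
                       a_fraction = 0.5, bs = NULL, seed = 1L) {
  stopifnot(genome_length >= n_chroms, snp_density >= 0,
            trtv_ratio > 0, read_length >= 1, depth >= 0,
            error_rate >= 0, error_rate <= 1,
            a_fraction >= 0, a_fraction <= 1)
  if (!is.null(bs)) {
    stopifnot(bs$conversion_rate >= 0, bs$conversion_rate <= 1,
              all(bs$methylation >= 0), all(bs$methylation <= 1),
              all(c("CG", "CHG", "CHH") %in% names(bs$methylation)))
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_chroms = as.integer(n_chroms),
                 snp_density = snp_density, trtv_ratio = trtv_ratio,
                 read_length = as.integer(read_length), depth = depth,
                 error_rate = error_rate, a_fraction = a_fraction,
                 bs = bs, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a diverged diploid genome pair
#'
#' Draws the D (reference) genome uniformly over A/C/G/T, then derives
#' the A genome by substituting bases at positions sampled uniformly at
#' the target density — at most one substitution per position. Each
#' substitution is a transition with probability r/(r+1) (r the target
#' ratio), else one of the two transversion partners with equal
#' probability.
#'
#' @param config A [sim_config()].
#' @return List with `reference` (named char vector, the D genome),
#'   `genome_A`, `truth` (data.table chrom, pos 0-based, ref_base,
#'   allele_A, allele_D, snp_type) and `config`.
#' @export
simulate_genomes <- function(config = sim_config()) {
  with_seed(config$seed, {
    chrom_len <- rep(config$genome_length %/% config$n_chroms,
                     config$n_chroms)
    chrom_len[1L] <- chrom_len[1L] + config$genome_length %% config$n_chroms
    names(chrom_len) <- paste0("chr", seq_len(config$n_chroms))
    reference <- vapply(chrom_len, function(len)
      paste(sample(BASES, len, replace = TRUE), collapse = ""), "")
    genome_A <- reference
    truth <- vector("list", config$n_chroms)
    p_tr <- config$trtv_ratio / (config$trtv_ratio + 1)
    for (k in seq_along(chrom_len)) {
      len <- chrom_len[k]
      n_snps <- round(len * config$snp_density / 1000)
      if (n_snps > len) {
        hs_usage_error("snp_density too high: %d SNPs on a %d bp chromosome",
                       n_snps, len)
      }
      if (n_snps == 0L) {
        truth[[k]] <- data.table(chrom = character(), pos = integer(),
                                 ref_base = character(),
                                 allele_A = character(),
                                 allele_D = character(),
                                 snp_type = character())
        next
      }
      pos <- sort(sample.int(len, n_snps)) - 1L
      ref_b <- substring(reference[k], pos + 1L, pos + 1L)
      is_tr <- stats::runif(n_snps) < p_tr
      alt <- character(n_snps)
      alt[is_tr] <- TRANSITION_PARTNER[ref_b[is_tr]]
      if (any(!is_tr)) {
        pick <- stats::runif(sum(!is_tr)) < 0.5
        tv <- t(vapply(TRANSVERSION_PARTNERS[ref_b[!is_tr]], identity,
                       character(2L)))
        alt[!is_tr] <- ifelse(pick, tv[, 1L], tv[, 2L])
      }
      sq <- strsplit(genome_A[k], "", fixed = TRUE)[[1L]]
      sq[pos + 1L] <- alt
      genome_A[k] <- paste(sq, collapse = "")
      truth[[k]] <- data.table(chrom = names(chrom_len)[k], pos = pos,
                               ref_base = ref_b, allele_A = alt,
                               allele_D = ref_b,
                               snp_type = ifelse(is_tr, "transition",
                                                 "transversion"))
    }
    list(reference = reference, genome_A = genome_A,
         truth = rbindlist(truth), config = config)
  })
}

#' Turn a simulator truth table into a homoeo-SNP index
#' @param sim Output of [simulate_genomes()].
#' @return A [snp_index()] of the true divergent sites.
#' @export
truth_index <- function(sim) {
  tr <- sim$truth
  if (nrow(tr) == 0L) return(snp_index(NULL, reference = "simulated"))
  snp_index(data.table(chrom = tr$chrom, pos = tr$pos,
                       ref_base = tr$ref_base, alleles_A = tr$allele_A,
                       alleles_D = tr$allele_D, snp_type = tr$snp_type,
                       origin = "diploid_pileup"),
            reference = "simulated",
            min_coverage = 4L, maf_threshold = 0.4,
            fixation_threshold = 0.9)
}

#' Simulate pre-aligned reads with truth labels
#'
#' Reads are drawn from the A and D genomes in the configured
#' proportion and emitted pre-aligned to the D reference at their true
#' coordinates (no indels; alignment itself is upstream of this
#' pipeline). Substitution errors are applied after sampling. Base
#' qualities are constant Phred 35 unless low-quality positions are
#' injected.
#'
#' @param sim Output of [simulate_genomes()].
#' @param n_reads Number of reads; default from configured depth.
#' @param seed_offset Added to the configured seed, letting independent
#'   read sets share one genome pair.
#' @return List with `aln` (header + reads, SAM layout) and `truth`
#'   (data.table qname, genome, chrom, start 0-based).
#' @export
simulate_reads <- function(sim, n_reads = NULL, seed_offset = 1L) {
  config <- sim$config
  chrom_len <- nchar(sim$reference)
  total_len <- sum(chrom_len)
  if (is.null(n_reads)) {
    n_reads <- max(1L, round(config$depth * total_len / config$read_length))
  }
  L <- config$read_length
  with_seed(config$seed + seed_offset, {
    genome <- sample(c("A", "D"), n_reads, replace = TRUE,
                     prob = c(config$a_fraction, 1 - config$a_fraction))
    chrom <- sample(names(chrom_len), n_reads, replace = TRUE,
                    prob = chrom_len / total_len)
    start <- vapply(chrom, function(ch)
      sample.int(chrom_len[[ch]] - L + 1L, 1L) - 1L, integer(1L))
    src <- ifelse(genome == "A", sim$genome_A[chrom], sim$reference[chrom])
    seqs <- substring(src, start + 1L, start + L)
    if (config$error_rate > 0) {
      n_err <- stats::rbinom(n_reads, L, config$error_rate)
      for (i in which(n_err > 0L)) {
        at <- sample.int(L, n_err[i])
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        s[at] <- vapply(s[at], function(b)
          sample(setdiff(BASES, b), 1L), "")
        seqs[i] <- paste(s, collapse = "")
      }
    }
    qname <- sprintf("r%06d", seq_len(n_reads))
    reads <- data.table(qname = qname, flag = 0L, rname = chrom,
                        pos = start + 1L, mapq = 60L,
                        cigar = paste0(L, "M"), rnext = "*", pnext = 0L,
                        tlen = 0L, seq = seqs, qual = strrep("D", L),
                        tags = "")
    setorder(reads, rname, pos, qname)
    truth <- data.table(qname = reads$qname,
                        genome = genome[match(reads$qname, qname)],
                        chrom = reads$rname, start = reads$pos - 1L)
    list(aln = list(header = sam_header_for(sim$reference, "coordinate"),
                    reads = reads),
         truth = truth)
  })
}

#' Apply bisulfite conversion to simulated reads
#'
#' Each read is assigned an origin strand (plus/minus with equal
#' probability). Cytosines of that strand — C in forward orientation on
#' plus-strand reads, G on minus-strand reads — are methylated
#' independently per read with their context's probability (context
#' taken from the read's genome of origin); unmethylated cytosines
#' convert with the configured rate (C->T on plus, G->A on minus).
#'
#' @param sim_reads Output of [simulate_reads()].
#' @param sim Output of [simulate_genomes()] (must carry `bs` config).
#' @param seed_offset Seed offset (default 2).
#' @return List with `aln` (converted reads), `truth` (read truth plus
#'   `bs_strand`) and `meth_truth` (per read-cytosine records).
#' @export
bisulfite_convert <- function(sim_reads, sim, seed_offset = 2L) {
  config <- sim$config
  if (is.null(config$bs)) hs_usage_error("config has no bisulfite settings")
  conv <- config$bs$conversion_rate
  meth <- config$bs$methylation
  reads <- copy(sim_reads$aln$reads)
  truth <- copy(sim_reads$truth)
  with_seed(config$seed + seed_offset, {
    strand <- sample(c("plus", "minus"), nrow(reads), replace = TRUE)
    meth_rows <- vector("list", nrow(reads))
    for (i in seq_len(nrow(reads))) {
      tr <- truth[i]
      src <- if (tr$genome == "A") sim$genome_A[[tr$chrom]] else
        sim$reference[[tr$chrom]]
      s <- strsplit(reads$seq[i], "", fixed = TRUE)[[1L]]
      tgt <- if (strand[i] == "plus") "C" else "G"
      offs <- which(s == tgt)
      # only true genome cytosines participate; error bases do not
      offs <- offs[substring(src, tr$start + offs, tr$start + offs) == tgt]
      if (length(offs) == 0L) {
        meth_rows[[i]] <- NULL
      } else {
        ctx <- vapply(offs, function(o)
          methylation_context(src, tr$start + o - 1L, strand[i]), "")
        p <- ifelse(ctx %in% names(meth), meth[ctx], 0)
        methylated <- stats::runif(length(offs)) < p
        converted <- !methylated & stats::runif(length(offs)) < conv
        if (any(converted)) {
          s[offs[converted]] <- if (strand[i] == "plus") "T" else "A"
          reads$seq[i] <- paste(s, collapse = "")
        }
        meth_rows[[i]] <- data.table(qname = reads$qname[i],
                                     chrom = tr$chrom,
                                     pos = tr$start + offs - 1L,
                                     strand = strand[i], context = ctx,
                                     methylated = methylated,
                                     converted = converted)
      }
    }
    truth[, bs_strand := strand]
    list(aln = list(header = sim_reads$aln$header, reads = reads),
         truth = truth,
         meth_truth = rbindlist(meth_rows[!vapply(meth_rows, is.null, TRUE)]))
  })
}

#' Build per-genome mpileup streams from truth-labeled reads
#'
#' Partitions reads by true genome of origin and piles them up against
#' the reference, emitting the 6-column samtools mpileup text dialect
#' ('.' for reference-matching bases, the base letter otherwise,
#' constant quality).
#'
#' @param sim_reads Output of [simulate_reads()].
#' @param reference Named character vector (the D reference).
#' @param out_A,out_D Optional output paths.
#' @return List with `pileup_A` and `pileup_D` (character vectors of
#'   mpileup lines).
#' @export
make_pileups <- function(sim_reads, reference, out_A = NULL, out_D = NULL) {
  reads <- sim_reads$aln$reads
  truth <- sim_reads$truth
  pile_one <- function(sub) {
    if (nrow(sub) == 0L) return(character())
    cols <- vector("list", nrow(sub))
    for (i in seq_len(nrow(sub))) {
      pairs <- read_to_reference_pairs(sub$pos[i], sub$cigar[i])
      cols[[i]] <- data.table(chrom = sub$rname[i], pos = pairs$ref_pos,
                              base = substring(sub$seq[i],
                                               pairs$read_offset + 1L,
                                               pairs$read_offset + 1L))
    }
    long <- rbindlist(cols)
    long[, ref := substring(reference[chrom], pos + 1L, pos + 1L)]
    agg <- long[, .(depth = .N,
                    bases = paste(ifelse(base == ref, ".", base),
                                  collapse = "")),
                by = .(chrom, pos, ref)]
    setorder(agg, chrom, pos)
    agg[, sprintf("%s\t%d\t%s\t%d\t%s\t%s", chrom, pos + 1L, ref, depth,
                  bases, strrep("I", depth))]
  }
  genome_of <- truth$genome[match(reads$qname, truth$qname)]
  pA <- pile_one(reads[genome_of == "A"])
  pD <- pile_one(reads[genome_of == "D"])
  if (!is.null(out_A)) writeLines(pA, out_A)
  if (!is.null(out_D)) writeLines(pD, out_D)
  list(pileup_A = pA, pileup_D = pD)
}

#' Export simulated reads as FASTQ (for users running a real aligner)
#' @param sim_reads Output of [simulate_reads()].
#' @param path Output path.
#' @export
write_fastq <- function(sim_reads, path) {
  reads <- sim_reads$aln$reads
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$qname, "\n", reads$seq, "\n+\n", reads$qual),
               con)
  }
  invisible(path)
}
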