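test_that("infer_strand counts conversions and is a total trichotomy", {
  ref <- c(chr1 = "ACCGGTAC")
  # read with C->T mismatches only
  r <- mk_read("chr1", 1, "8M", "ATTGGTAC")
  s <- infer_strand(r, ref)
  expect_equal(s$strand, "plus")
  expect_equal(s$n_ct, 2L)
  expect_equal(s$n_ga, 0L)

  r <- mk_read("chr1", 1, "8M", "ACCAGTAC")
  s <- infer_strand(r, ref)
  expect_equal(s$strand, "minus")
  expect_equal(s$n_ga, 1L)

  r <- mk_read("chr1", 1, "8M", "ATCGATAC")  # one C->T, one G->A
  expect_equal(infer_strand(r, ref)$strand, "ambiguous")
  # no conversions at all is also ambiguous
  expect_equal(infer_strand(mk_read("chr1", 1, "8M", "ACCGGTAC"), ref)$strand,
               "ambiguous")
})

test_that("indexed SNP positions are excluded from conversion counting", {
  ref <- c(chr1 = "ACCGGTAC")
  idx <- snp_index(data.table(chrom = "chr1", pos = 1L, ref_base = "C",
                              alleles_A = "T", alleles_D = "C",
                              snp_type = "transition"),
                   reference = "chr1")
  r <- mk_read("chr1", 1, "8M", "ATCGGTAC")   # T at the indexed C/T SNP
  expect_equal(infer_strand(r, ref)$n_ct, 1L)
  expect_equal(infer_strand(r, ref, idx)$n_ct, 0L)
})

test_that("bs_match reproduces the strand-conditional worked examples", {
  # C (A genome) vs T (D genome): a read T on the plus strand could be an
  # unmethylated converted C, so the site is uninformative there...
  expect_equal(bs_match("T", "C", "T", "plus"), "uninformative_strand")
  # ...but on the minus strand a T is unambiguously the D allele
  expect_equal(bs_match("T", "C", "T", "minus"), "matches_D")
  # G vs T site read on the minus strand: an A is a converted G -> A genome
  expect_equal(bs_match("A", "G", "T", "minus"), "matches_A")

  # conversion tolerance: plus-strand T matches a C allele
  expect_equal(bs_match("T", "C", "G", "plus"), "matches_A")
  expect_equal(bs_match("T", "G", "C", "plus"), "matches_D")
  # exact matches always work
  expect_equal(bs_match("G", "G", "T", "plus"), "matches_A")
  expect_equal(bs_match("C", "A", "G", "plus"), "matches_neither")
  # G/A confound on the minus strand, fine on plus
  expect_equal(bs_match("G", "G", "A", "minus"), "uninformative_strand")
  expect_equal(bs_match("G", "G", "A", "plus"), "matches_A")
  # multi-allele sets confound set-wise
  expect_equal(bs_match("T", "C,G", "T", "plus"), "uninformative_strand")
})

test_that("ambiguous-strand reads keep only sites where both hypotheses agree", {
  # reference with no C or G outside the SNP: strand stays ambiguous
  ref <- c(chr1 = "ATTCTTAT")
  idx <- snp_index(data.table(chrom = "chr1", pos = 3L, ref_base = "C",
                              alleles_A = "C", alleles_D = "T",
                              snp_type = "transition"))
  # read base C at a C/T SNP: minus-hypothesis says matches_A, but the
  # plus-hypothesis calls the site uninformative -> disagreement -> N
  r <- mk_read("chr1", 1, "8M", "ATTCTTAT")
  res <- evaluate_bs_read(r, idx, ref)
  expect_equal(res$strand, "ambiguous")
  expect_equal(res$site_verdicts, "uninformative_strand")
  expect_equal(res$category, "N")

  # a transversion SNP is informative under both hypotheses
  idx2 <- snp_index(data.table(chrom = "chr1", pos = 3L, ref_base = "C",
                               alleles_A = "C", alleles_D = "G",
                               snp_type = "transversion"))
  res2 <- evaluate_bs_read(r, idx2, ref)
  expect_equal(res2$category, "A")
})

test_that("BS informative sites are a subset of standard-mode sites", {
  cfg <- sim_config(genome_length = 15000L, depth = 3, error_rate = 0,
                    seed = 51,
                    bs = list(conversion_rate = 1,
                              methylation = c(CG = 0.8, CHG = 0.5,
                                              CHH = 0.05)))
  sim <- simulate_genomes(cfg)
  rds <- simulate_reads(sim, n_reads = 300L)
  bs <- bisulfite_convert(rds, sim)
  idx <- truth_index(sim)
  lk <- homeosort:::index_lookup(idx)
  ccfg <- categorizer_config()
  for (i in seq_len(nrow(bs$aln$reads))) {
    row <- as.list(bs$aln$reads[i])
    ev <- evaluate_bs_read(row, lk, sim$reference, ccfg)
    std <- genotype_read(row, lk, ccfg)
    informative_bs <- ev$sites$pos[ev$site_verdicts %in%
                                     c("matches_A", "matches_D")]
    informative_std <- std$pos
    expect_true(all(informative_bs %in% informative_std))
  }
})

test_that("unconverted libraries at transversion SNPs match standard mode", {
  cfg <- sim_config(genome_length = 10000L, depth = 3, error_rate = 0,
                    trtv_ratio = 1e-9,  # essentially all transversions
                    seed = 53,
                    bs = list(conversion_rate = 0,
                              methylation = c(CG = 1, CHG = 1, CHH = 1)))
  sim <- simulate_genomes(cfg)
  expect_true(all(sim$truth$snp_type == "transversion"))
  rds <- simulate_reads(sim, n_reads = 200L)
  bs <- bisulfite_convert(rds, sim)
  # full methylation + zero conversion: reads unchanged
  expect_identical(bs$aln$reads$seq, rds$aln$reads$seq)
  idx <- truth_index(sim)
  std <- partition_alignment(rds$aln, idx)
  bsm <- partition_alignment(bs$aln, idx, bs = TRUE,
                             reference = sim$reference)
  # C/G-containing transversion SNPs can still be strand-confounded for
  # one strand... only pure A-T/C-G... compare read-for-read where BS
  # called a genome: those calls must agree with standard mode
  called <- bsm$reads[category %in% c("A", "D")]
  m <- merge(called[, .(qname, category)],
             std$reads[, .(qname, std_cat = category)], by = "qname")
  expect_true(all(m$category == m$std_cat))
})

test_that("methylation_context resolves CG/CHG/CHH and contig edges", {
  expect_equal(methylation_context("ACGTT", 1L, "plus"), "CG")
  expect_equal(methylation_context("ACAGT", 1L, "plus"), "CHG")
  expect_equal(methylation_context("ACATT", 1L, "plus"), "CHH")
  # minus strand mirrors on the reverse complement
  expect_equal(methylation_context("ACGTT", 2L, "minus"), "CG")
  expect_equal(methylation_context("CCTGA", 3L, "minus"), "CHG")
  expect_equal(methylation_context("TTTGA", 3L, "minus"), "CHH")
  # edges: resolvable prefix wins, otherwise NA
  expect_equal(methylation_context("ACG", 1L, "plus"), "CG")
  expect_equal(methylation_context("AAC", 2L, "plus"), "NA")
  expect_equal(methylation_context("ACA", 1L, "plus"), "NA")
  expect_error(methylation_context("AAAA", 0L, "plus"), "not C")
})

test_that("methylation report conserves per-category counts incl. half reads", {
  ref <- c(chr1 = "TTCGTTTTAACGTT")
  idx <- snp_index(data.table(chrom = "chr1", pos = 0L, ref_base = "T",
                              alleles_A = "A", alleles_D = "T",
                              snp_type = "transversion"))
  # plus-strand read (has a C->T conversion at pos 10), covers C at 2
  r1 <- mk_read("chr1", 1, "14M", "TTCGTTTTAATGTT", qname = "b1")
  # ambiguous read: no conversions, base C at both C sites
  r2 <- mk_read("chr1", 1, "14M", "TTCGTTTTAACGTT", qname = "b2")
  aln <- mk_alignment(list(r1, r2), ref)
  rep_dt <- methylation_report(aln, ref, idx)
  site2 <- rep_dt[pos == 2L & strand == "plus"]
  expect_equal(site2$context, "CG")
  # r1 weight 1 (plus), r2 weight 0.5 (ambiguous)
  expect_equal(site2$total_unconverted, 1.5)
  site10 <- rep_dt[pos == 10L & strand == "plus"]
  expect_equal(site10$total_converted, 1)      # r1 converted
  expect_equal(site10$total_unconverted, 0.5)  # r2 half-read
  # per-category columns sum to totals at every site
  expect_equal(rep_dt$total_unconverted,
               rep_dt$unconv_A + rep_dt$unconv_D + rep_dt$unconv_X +
                 rep_dt$unconv_N)
  expect_equal(rep_dt$total_converted,
               rep_dt$conv_A + rep_dt$conv_D + rep_dt$conv_X + rep_dt$conv_N)
})

test_that("simulated methylation levels are recovered per context", {
  # scaled for test runtime: small genome at high depth; the acceptance
  # suite runs the full 500x configuration
  cfg <- sim_config(genome_length = 2000L, depth = 60, error_rate = 0,
                    seed = 55,
                    bs = list(conversion_rate = 1,
                              methylation = c(CG = 0.8, CHG = 0.5,
                                              CHH = 0.05)))
  sim <- simulate_genomes(cfg)
  rds <- simulate_reads(sim)
  bs <- bisulfite_convert(rds, sim)
  idx <- truth_index(sim)
  rep_dt <- methylation_report(bs$aln, sim$reference, idx)
  est <- rep_dt[context %in% c("CG", "CHG", "CHH"),
                .(level = sum(total_unconverted) /
                    sum(total_unconverted + total_converted),
                  n = sum(total_unconverted + total_converted)),
                by = context]
  truth_p <- c(CG = 0.8, CHG = 0.5, CHH = 0.05)
  for (ctx in est$context) {
    p <- truth_p[[ctx]]
    n <- est[context == ctx, n]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(est[context == ctx, level] - p), 3 * se + 1e-9,
              label = sprintf("context %s", ctx))
  }
})

test_that("bisulfite simulation respects its own invariants", {
  cfg <- sim_config(genome_length = 3000L, depth = 10, error_rate = 0,
                    seed = 57,
                    bs = list(conversion_rate = 1,
                              methylation = c(CG = 0, CHG = 0, CHH = 0)))
  sim <- simulate_genomes(cfg)
  rds <- simulate_reads(sim, n_reads = 50L)
  bs <- bisulfite_convert(rds, sim)
  # methylation 0, conversion 1: every origin-genome C (plus) / G (minus)
  # is converted
  for (i in seq_len(nrow(bs$aln$reads))) {
    tr <- bs$truth[i]
    src <- if (tr$genome == "A") sim$genome_A[[tr$chrom]] else
      sim$reference[[tr$chrom]]
    seg <- substring(src, tr$start + 1L, tr$start + nchar(bs$aln$reads$seq[i]))
    s <- strsplit(bs$aln$reads$seq[i], "")[[1L]]
    g <- strsplit(seg, "")[[1L]]
    if (tr$bs_strand == "plus") {
      expect_false(any(s == "C" & g == "C"))
    } else {
      expect_false(any(s == "G" & g == "G"))
    }
  }
})
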