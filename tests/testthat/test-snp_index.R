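test_that("call_site applies coverage, MAF and fixation rules", {
  # clean fixed difference
  r <- call_site(c(G = 10), c(A = 8), 4, 0.4, 0.9)
  expect_equal(r$verdict, "homoeo_snp")
  expect_equal(r$alleles_A, "G")
  expect_equal(r$alleles_D, "A")
  expect_equal(r$snp_type, "transition")

  # below-coverage sites are excluded
  expect_equal(call_site(c(G = 3), c(A = 8))$verdict, "no_call")

  # within-genome polymorphism with a base shared with the other genome:
  # the shared base is removed where it is minor, leaving a single-allele
  # homoeo-SNP plus an allele-SNP annotation for the polymorphic genome
  r <- call_site(c(G = 6, A = 4), c(A = 8))
  expect_equal(r$verdict, "homoeo_snp")
  expect_equal(r$alleles_A, "G")
  expect_equal(r$alleles_D, "A")
  expect_equal(r$snp_type, "transition")
  expect_equal(r$allele_snp, "A")

  # genuine multi-allele homoeo-SNP (no sharing)
  r <- call_site(c(C = 6, T = 4), c(A = 10))
  expect_equal(r$verdict, "homoeo_snp")
  expect_equal(r$snp_type, "multi_allele")
  expect_equal(r$alleles_A, c("C", "T"))

  # same fixed base in both genomes: nothing to index
  expect_equal(call_site(c(A = 10), c(A = 12))$verdict, "no_call")

  # polymorphic genome whose shared base is the other genome's major
  # allele too: site cannot discriminate, but the polymorphism is noted
  r <- call_site(c(G = 6, A = 4), c(G = 10))
  expect_equal(r$verdict, "allele_snp_A")
  expect_equal(r$alleles_A, c("A", "G"))

  # position mismatch between pileup columns is a contract violation
  ca <- parse_mpileup_line("chr1\t10\tA\t4\tGGGG\tIIII")
  cd <- parse_mpileup_line("chr1\t11\tA\t4\t....\tIIII")
  expect_error(call_site(ca, cd), "different positions")
})

test_that("raising thresholds never adds calls (monotonicity)", {
  set.seed(5)
  for (i in 1:50) {
    cA <- stats::setNames(rpois(4, 3), c("A", "C", "G", "T"))
    cD <- stats::setNames(rpois(4, 3), c("A", "C", "G", "T"))
    v1 <- call_site(cA, cD, min_coverage = 4)$verdict
    v2 <- call_site(cA, cD, min_coverage = 8)$verdict
    if (v2 == "homoeo_snp") expect_equal(v1, "homoeo_snp")
    h1 <- call_site(cA, cD, fixation_threshold = 0.7)$verdict
    h2 <- call_site(cA, cD, fixation_threshold = 0.95)$verdict
    if (h2 == "homoeo_snp" && h1 != "homoeo_snp") {
      fail(sprintf("fixation monotonicity violated: %s", paste(cA, cD)))
    }
  }
})

test_that("classify_snp distinguishes transitions, transversions, multi", {
  expect_equal(classify_snp("A", "G"), "transition")
  expect_equal(classify_snp("C", "T"), "transition")
  expect_equal(classify_snp("C", "G"), "transversion")
  expect_equal(classify_snp("A", c("C", "T")), "multi_allele")
  expect_error(classify_snp("A", "A"), "overlap")
  expect_error(classify_snp("A", character()), "empty")
})

test_that("classification is invariant under complement", {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  bases <- c("A", "C", "G", "T")
  for (a in bases) for (d in setdiff(bases, a)) {
    expect_equal(classify_snp(a, d),
                 classify_snp(comp[[a]], comp[[d]]),
                 info = paste(a, d))
  }
})

test_that("index_summary conserves counts and handles edge cases", {
  idx <- toy_index()
  s <- index_summary(idx)
  expect_equal(s$transitions, 2)
  expect_equal(s$transversions, 1)
  expect_equal(s$total, 3)
  expect_equal(s$transitions + s$transversions + s$multi_allele, s$total)

  empty <- snp_index()
  s0 <- index_summary(empty)
  expect_equal(s0$total, 0)
  expect_true(is.nan(s0$titv_ratio))

  one <- snp_index(data.table(chrom = "c", pos = 0L, ref_base = "A",
                              alleles_A = "A", alleles_D = "G",
                              snp_type = "transition"))
  s1 <- index_summary(one)
  expect_equal(s1$transitions, 1)
  expect_true(is.nan(s1$titv_ratio))

  multi <- snp_index(data.table(chrom = "c", pos = c(0L, 5L),
                                ref_base = "A",
                                alleles_A = c("A", "C,T"),
                                alleles_D = c("G", "G"),
                                snp_type = c("transition", "multi_allele")))
  sm <- index_summary(multi)
  expect_equal(sm$multi_allele, 1)
  expect_equal(sm$total, 2)
})

test_that("snp_index enforces its invariants", {
  expect_error(snp_index(data.table(
    chrom = c("c", "c"), pos = c(3L, 3L), ref_base = "A",
    alleles_A = c("G", "G"), alleles_D = c("A", "T"),
    snp_type = "transition")), "duplicate")
  expect_error(snp_index(data.table(
    chrom = "c", pos = 3L, ref_base = "A",
    alleles_A = "G", alleles_D = "G,T", snp_type = "transition")),
    "intersect")
})

test_that("build_index equals per-position call_site on simulated columns", {
  sim <- simulate_genomes(sim_config(genome_length = 10000L, depth = 12,
                                     error_rate = 0.002, seed = 21))
  rds <- simulate_reads(sim)
  p <- make_pileups(rds, sim$reference)
  res <- build_index(p$pileup_A, p$pileup_D, reference = "simulated")

  # brute force: re-call every shared position independently
  pa <- read_mpileup(p$pileup_A)
  pd <- read_mpileup(p$pileup_D)
  shared <- merge(pa, pd, by = c("chrom", "pos"), suffixes = c(".A", ".D"))
  got <- as.data.table(res$index)
  n_brute <- 0L
  for (i in seq_len(nrow(shared))) {
    cA <- unlist(shared[i, .(A = nA.A, C = nC.A, G = nG.A, T = nT.A)])
    cD <- unlist(shared[i, .(A = nA.D, C = nC.D, G = nG.D, T = nT.D)])
    v <- call_site(cA, cD)
    if (v$verdict == "homoeo_snp") {
      n_brute <- n_brute + 1L
      row <- got[chrom == shared$chrom[i] & pos == shared$pos[i]]
      expect_equal(nrow(row), 1L)
      expect_equal(row$alleles_A, paste(v$alleles_A, collapse = ","))
      expect_equal(row$alleles_D, paste(v$alleles_D, collapse = ","))
    }
  }
  expect_equal(nrow(got), n_brute)
})

test_that("build_index recovers simulated truth exactly in the error-free regime", {
  sim <- simulate_genomes(sim_config(genome_length = 20000L, depth = 12,
                                     error_rate = 0, seed = 9))
  rds <- simulate_reads(sim)
  p <- make_pileups(rds, sim$reference)
  res <- build_index(p$pileup_A, p$pileup_D, reference = "simulated")
  pa <- read_mpileup(p$pileup_A)
  pd <- read_mpileup(p$pileup_D)
  shared <- merge(pa, pd, by = c("chrom", "pos"), suffixes = c(".A", ".D"))
  deep <- shared[(nA.A + nC.A + nG.A + nT.A) >= 4 &
                   (nA.D + nC.D + nG.D + nT.D) >= 4]
  truth_deep <- merge(sim$truth, deep[, .(chrom, pos)], by = c("chrom", "pos"))
  got <- as.data.table(res$index)
  expect_equal(nrow(got), nrow(truth_deep))
  m <- merge(got, truth_deep, by = c("chrom", "pos"))
  expect_equal(nrow(m), nrow(truth_deep))
  expect_true(all(m$alleles_A == m$allele_A & m$alleles_D == m$allele_D))
})

test_that("build_index rejects unsorted pileups and handles disjoint streams", {
  lines_ok <- c("chr1\t5\tA\t4\tGGGG\tIIII", "chr1\t9\tA\t4\tGGGG\tIIII")
  lines_bad <- rev(lines_ok)
  other <- c("chr1\t5\tA\t4\t....\tIIII", "chr1\t9\tA\t4\t....\tIIII")
  expect_error(build_index(lines_bad, other), "sorted")
  r <- build_index(lines_ok, other)
  expect_equal(nrow(r$index), 2L)
  disjoint <- build_index("chr1\t5\tA\t4\tGGGG\tIIII",
                          "chr1\t6\tA\t4\t....\tIIII")
  expect_equal(nrow(disjoint$index), 0L)
})

test_that("index round-trips losslessly and read_index validates", {
  p <- withr::local_tempfile(fileext = ".tsv")
  idx <- toy_index()
  write_index(idx, p)
  back <- read_index(p)
  expect_equal(as.data.table(back), as.data.table(idx))
  expect_equal(attr(back, "metadata"), attr(idx, "metadata"))

  lines <- readLines(p)
  writeLines(c(lines, lines[length(lines)]), p)   # duplicate position
  expect_error(read_index(p), "duplicate")

  writeLines(c(lines[1:5], "chr1\t10\tA\tG\tG,T\ttransition\tx"), p)
  expect_error(read_index(p), "intersect")
})

test_that("merge_indexes unions allele sets and masks conflicts", {
  idx <- toy_index()
  empty <- snp_index(NULL, reference = "toy")
  expect_equal(as.data.table(merge_indexes(idx, empty)), as.data.table(idx))
  expect_equal(as.data.table(merge_indexes(idx, idx)), as.data.table(idx))

  base <- snp_index(data.table(chrom = "c", pos = 3L, ref_base = "C",
                               alleles_A = "C", alleles_D = "T",
                               snp_type = "transition"), reference = "r")
  add <- snp_index(data.table(chrom = "c", pos = 3L, ref_base = "C",
                              alleles_A = "C", alleles_D = "G",
                              snp_type = "transversion"), reference = "r")
  m <- merge_indexes(base, add)
  expect_equal(m$alleles_D, "G,T")
  expect_equal(m$snp_type, "multi_allele")
  expect_equal(m$origin, "merged")

  conflict <- snp_index(data.table(chrom = "c", pos = 3L, ref_base = "C",
                                   alleles_A = "T", alleles_D = "A",
                                   snp_type = "transversion"),
                        reference = "r")
  expect_message(m2 <- merge_indexes(base, conflict), "dropped 1")
  expect_equal(nrow(m2), 0L)

  other_ref <- snp_index(NULL, reference = "other")
  expect_error(merge_indexes(base, other_ref), "different references")
})

test_that("export_gsnap writes the SNP-tolerant mapper dialect", {
  p <- withr::local_tempfile()
  idx <- snp_index(data.table(chrom = "chr1", pos = 9L, ref_base = "A",
                              alleles_A = "G", alleles_D = "A",
                              snp_type = "transition"))
  export_gsnap(idx, p)
  expect_equal(readLines(p), ">s1 chr1:10 AG")

  export_gsnap(snp_index(), p)
  expect_equal(readLines(p), character())

  multi <- snp_index(data.table(chrom = "chr1", pos = 9L, ref_base = "A",
                                alleles_A = "A", alleles_D = "C,T",
                                snp_type = "multi_allele"))
  export_gsnap(multi, p)
  expect_setequal(readLines(p), c(">s1 chr1:10 AC", ">s2 chr1:10 AT"))

  nonref <- snp_index(data.table(chrom = "chr1", pos = 0L, ref_base = "A",
                                 alleles_A = "G", alleles_D = "C",
                                 snp_type = "transversion"))
  expect_message(export_gsnap(nonref, p), "no reference-matching")
  expect_setequal(readLines(p), c(">s1 chr1:1 AG", ">s2 chr1:1 AC"))
})
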