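test_that("codon_alignment enforces frame, whole-codon gaps and no stops", {
  expect_s3_class(codon_alignment("ATGGCT", "ATG---"), "codon_alignment")
  expect_error(codon_alignment("ATGG", "ATGG"), "divisible by 3")
  expect_error(codon_alignment("ATGGCT", "ATG"), "length")
  expect_error(codon_alignment("ATG-CT", "ATGGCT"), "whole codons")
  expect_error(codon_alignment("ATGTAAGCT", "ATGTAAGCT"), "stop codon")
})

test_that("codon threading replaces residues by source codons and gaps by ---", {
  aln <- thread_codon_alignment("MA", "MA", "ATGGCT", "ATGGCA")
  expect_equal(aln$rows, c("ATGGCT", "ATGGCA"))

  aln2 <- thread_codon_alignment("M-A", "MKA", "ATGGCT", "ATGAAAGCA")
  expect_equal(aln2$rows, c("ATG---GCT", "ATGAAAGCA"))

  # terminal stop codons are trimmed before threading
  aln3 <- thread_codon_alignment("MA", "MA", "ATGGCTTAA", "ATGGCA")
  expect_equal(aln3$rows, c("ATGGCT", "ATGGCA"))
})

test_that("codon threading reports the first mismatching residue", {
  expect_error(thread_codon_alignment("MA", "MA", "ATGGTT", "ATGGCA"),
               "residue 2")
  expect_error(thread_codon_alignment("MAV", "MAV", "ATGGCTGCT", "ATGGCTGTT"),
               "residue 3")
  expect_error(thread_codon_alignment("MA", "MA", "ATGGC", "ATGGCA"),
               "divisible by 3")
})

test_that("4D sites require prefix agreement and a fourfold prefix", {
  expect_equal(identify_4d_sites(codon_alignment("GCTCGTGGA", "GCACGTGGG")),
               c(3L, 6L, 9L))
  expect_equal(identify_4d_sites(codon_alignment("ATGATG", "ATGATG")),
               integer(0))
  # differing prefixes (GCT vs ACT) disqualify the column
  expect_equal(identify_4d_sites(codon_alignment("GCT", "ACT")), integer(0))
  # gap and N codons are excluded
  expect_equal(identify_4d_sites(codon_alignment("GCTGCT", "---GCN")),
               integer(0))
})

test_that("fourDTv matches the hand-counted example and boundary cases", {
  f <- fourDTv(codon_alignment("GCTCGTGGA", "GCACGTGGG"))
  expect_equal(f$n_4d_sites, 3L)
  expect_equal(f$fourDTv_raw, 1 / 3)
  expect_equal(f$fourDTv_corrected, -0.5 * log(1 / 3))

  ident <- fourDTv(codon_alignment("GCTCGT", "GCTCGT"))
  expect_identical(ident$fourDTv_raw, 0)
  expect_identical(ident$fourDTv_corrected, 0)

  # raw = 0.5 saturates the log correction
  sat <- fourDTv(codon_alignment("GCTGCT", "GCAGCT"))
  expect_equal(sat$fourDTv_raw, 0.5)
  expect_true(sat$saturated)
  expect_true(is.na(sat$fourDTv_corrected))

  expect_error(fourDTv(codon_alignment("ATG", "ATG")), "fourfold")
})

test_that("4DTv correction is pluggable and corrected >= raw on [0, 0.5)", {
  raw_only <- fourDTv(codon_alignment("GCTCGTGGA", "GCACGTGGG"),
                      correction = "none")
  expect_equal(raw_only$fourDTv_corrected, raw_only$fourDTv_raw)
  q <- seq(0, 0.49, by = 0.01)
  corr <- -0.5 * log(1 - 2 * q)
  expect_true(all(corr >= q))
  expect_true(all(diff(corr) > 0))
})

test_that("4DTv is invariant to swapping the two rows", {
  set.seed(11)
  for (r in 1:10) {
    pr <- evolve_codon_pair(60, 0.4, 2, omega = 0.5)
    a <- fourDTv(codon_alignment(pr$a, pr$b))
    b <- fourDTv(codon_alignment(pr$b, pr$a))
    expect_identical(a$fourDTv_raw, b$fourDTv_raw)
    expect_identical(a$n_4d_sites, b$n_4d_sites)
  }
})

test_that("NG86 reproduces the hand-computed single-difference example", {
  k <- ng86_kaks(codon_alignment("AAAAATGGG", "AAAAACGGG"))
  expect_equal(k$S, 5 / 3)
  expect_equal(k$N, 22 / 3)
  expect_equal(k$Sd, 1)
  expect_equal(k$Nd, 0)
  expect_equal(k$ps, 0.6)
  expect_equal(k$Ks, -0.75 * log(0.2))
  expect_equal(k$Ka, 0)
  expect_equal(k$omega, 0)
})

test_that("NG86 on identical sequences gives Ka = Ks = 0 and undefined omega", {
  k <- ng86_kaks(codon_alignment("ATGGCTCGT", "ATGGCTCGT"))
  expect_identical(k$Ka, 0)
  expect_identical(k$Ks, 0)
  expect_true(is.na(k$omega))
})

test_that("NG86 excludes gap and ambiguous codons and flags saturation", {
  with_gap <- ng86_kaks(codon_alignment("AAAAATGGG---", "AAAAACGGGCCC"))
  no_gap <- ng86_kaks(codon_alignment("AAAAATGGG", "AAAAACGGG"))
  expect_equal(with_gap$S, no_gap$S)
  expect_equal(with_gap$n_codons_used, 3L)
  with_n <- ng86_kaks(codon_alignment("AAAAATGGGNCC", "AAAAACGGGCCC"))
  expect_equal(with_n$Sd, no_gap$Sd)
  # every codon synonymous-different: ps = 3 >= 3/4
  expect_error(ng86_kaks(codon_alignment("AAAAAA", "AAGAAG")), "saturation")
})

test_that("NG86 agrees with the pathway-enumeration oracle on random alignments", {
  set.seed(20)
  for (r in 1:8) {
    pr <- evolve_codon_pair(20, 0.5, 2, omega = 0.5)
    mine <- ng86_kaks(codon_alignment(pr$a, pr$b))
    ref <- oracle_ng86(pr$a, pr$b)
    expect_equal(mine$S, ref$S)
    expect_equal(mine$Sd, ref$Sd)
    expect_equal(mine$Nd, ref$Nd)
    expect_equal(mine$Ka, ref$Ka)
    expect_equal(mine$Ks, ref$Ks)
  }
})

test_that("pairwise identity counts only gap-free columns", {
  expect_equal(pairwise_identity("ACGT", "ACGA"), 75)
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  expect_equal(pairwise_identity("AC-T", "ACGT"), 100)
  expect_error(pairwise_identity("--", "A-"), "comparable")
})

test_that("divergence_profile classifies recent/intermediate/ancient cohorts", {
  one <- function(corr) structure(
    list(n_4d_sites = 10L, n_4d_transversions = 0L, Q = 0,
         fourDTv_raw = 0, fourDTv_corrected = corr, saturated = FALSE),
    class = "fourdtv")
  prof <- divergence_profile(list(one(0.6), one(0.005), one(0.2)))
  expect_equal(unname(prof$counts[c("ancient", "recent", "intermediate")]),
               c(1L, 1L, 1L))

  # simulated cohort with known branch lengths lands in the right classes
  set.seed(31)
  alns <- lapply(c(0.001, 0.15, 1.5), function(d) {
    pr <- evolve_codon_pair(2000, d, 2, omega = 1)
    codon_alignment(pr$a, pr$b)
  })
  prof2 <- divergence_profile(alns)
  expect_equal(prof2$estimates$class,
               c("recent", "intermediate", "ancient"))
})

test_that("omega recovery: NG86 is calibrated on neutral simulated cohorts", {
  # kappa = 1 matches the estimator's unweighted mutation assumption
  set.seed(17)
  omegas <- vapply(1:200, function(r) {
    pr <- evolve_codon_pair(3000, 0.3, 1, omega = 1)
    ng86_kaks(codon_alignment(pr$a, pr$b))$omega
  }, numeric(1))
  expect_gt(mean(omegas), 0.9)
  expect_lt(mean(omegas), 1.1)
})

test_that("fully constrained cohorts drive Ka toward 0", {
  # omega = 0 admits no amino-acid changes; the only nonzero Nd can come from
  # pathway averaging when two synonymous hits land in one codon, a
  # second-order effect in d
  set.seed(23)
  for (r in 1:5) {
    pr <- evolve_codon_pair(500, 0.3, 2, omega = 0)
    expect_identical(pr$truth$n_nonsyn, 0L)
    k <- ng86_kaks(codon_alignment(pr$a, pr$b))
    expect_lt(k$Ka, 0.01)
    expect_gt(k$Ks, 0.1)
  }
})

test_that("estimate_divergence runs end to end on a paralog-like pair", {
  pr <- evolve_codon_pair(150, 0.1, 2, omega = 0.1, seed = 41)
  est <- estimate_divergence(pr$a, pr$b)
  expect_gt(est$nt_identity_pct, 90)
  expect_gte(est$aa_identity_pct, est$nt_identity_pct)
  expect_s3_class(est$fourdtv, "fourdtv")
  expect_s3_class(est$ng86, "ng86")
  expect_output(print(est), "identity")
})
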