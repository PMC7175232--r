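test_that("evolve_codon_pair: d = 0 gives identical stop-free sequences", {
  pr <- evolve_codon_pair(40, 0, 2, seed = 1)
  expect_identical(pr$a, pr$b)
  expect_equal(pr$truth$n_syn + pr$truth$n_nonsyn, 0L)
  expect_equal(nchar(pr$a), 120L)
})

test_that("evolve_codon_pair is deterministic under a fixed seed", {
  p1 <- evolve_codon_pair(100, 0.4, 2, omega = 0.3, seed = 99)
  p2 <- evolve_codon_pair(100, 0.4, 2, omega = 0.3, seed = 99)
  expect_identical(p1, p2)
  p3 <- evolve_codon_pair(100, 0.4, 2, omega = 0.3, seed = 100)
  expect_false(identical(p1$a, p3$a))
})

test_that("evolve_codon_pair never emits stop codons", {
  stops <- c("TAA", "TAG", "TGA")
  set.seed(7)
  for (r in 1:10) {
    pr <- evolve_codon_pair(80, 1.0, 2, omega = runif(1))
    for (s in c(pr$a, pr$b)) {
      cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      expect_false(any(cods %in% stops))
    }
  }
})

test_that("evolve_codon_pair rejects invalid configurations", {
  expect_error(evolve_codon_pair(10, -0.1, 2), "d must")
  expect_error(evolve_codon_pair(10, 0.1, 0), "kappa")
  expect_error(evolve_codon_pair(0, 0.1, 2), "n_codons")
  expect_error(evolve_codon_pair(10, 0.1, 2, omega = -1), "omega")
})

test_that("evolve_codon_pair records constraint in realized truth counts", {
  pr <- evolve_codon_pair(800, 0.3, 2, omega = 0, seed = 5)
  expect_equal(pr$truth$n_nonsyn, 0L)
  expect_gt(pr$truth$n_syn, 0L)
  pr1 <- evolve_codon_pair(800, 0.3, 2, omega = 1, seed = 5)
  expect_gt(pr1$truth$n_nonsyn, 0L)
})

test_that("simulate_snp_panel: theta = 0 gives an empty panel with pi = 0", {
  pan <- simulate_snp_panel(50, 1000, 0, seed = 2)
  expect_equal(nrow(pan$sites), 0)
  expect_identical(pan$truth_pi, 0)
  expect_identical(pi_gene(pan$sites, 1000, "per_site")$pi, 0)
})

test_that("simulate_snp_panel: n = 2 sites all have frequency 1/2 and
           truth_pi equals the direct pairwise count", {
  pan <- simulate_snp_panel(2, 100, 0.05, seed = 4)
  expect_gt(nrow(pan$sites), 0)
  for (ct in pan$sites$allele_counts) expect_equal(unname(ct), c(1L, 1L))
  # one pair of haplotypes: pi is the raw difference count over L
  expect_equal(pan$truth_pi, sum(pan$genotypes[1, ] != pan$genotypes[2, ]) / 100)
})

test_that("simulate_snp_panel truth_pi is realized, matching the emitted counts", {
  for (seed in 1:5) {
    pan <- simulate_snp_panel(30, 2000, 0.01, seed = seed)
    expect_identical(pi_gene(pan$sites, pan$L, "per_site")$pi, pan$truth_pi)
    expect_false(any(duplicated(pan$sites$pos)))
    # genotype matrix is consistent with the allele counts
    alt_counts <- vapply(pan$sites$allele_counts, function(ct) ct[[2]], 0L)
    expect_equal(unname(colSums(pan$genotypes)), alt_counts,
                 ignore_attr = TRUE)
  }
})

test_that("fixed-frequency SFS plants every site at the requested frequency", {
  pan <- simulate_snp_panel(20, 500, 0.02, sfs_model = "fixed_frequency",
                            f = 0.25, seed = 6)
  for (ct in pan$sites$allele_counts) expect_equal(ct[[2]], 5L)
  expect_error(simulate_snp_panel(20, 500, 0.02,
                                  sfs_model = "fixed_frequency", f = 1.2))
  expect_error(simulate_snp_panel(20, 500, -0.1), "theta")
})

test_that("panel VCF writer round-trips through the VCF reader", {
  ann <- data.frame(effect = c("missense_variant", "synonymous_variant"),
                    impact = c("MODERATE", "LOW"), prob = c(0.5, 0.5),
                    stringsAsFactors = FALSE)
  pan <- simulate_snp_panel(12, 400, 0.03, seed = 8, ann_classes = ann)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(pan, f, gene_id = "gX")
  back <- read_vcf_interval(f, "sim1", 1, 400, gene_id = "gX")
  expect_equal(back$pos, pan$sites$pos)
  expect_equal(back$impact, pan$sites$impact)
  expect_equal(back$effect, pan$sites$effect)
  for (j in seq_len(nrow(back))) {
    expect_equal(sort(unname(back$allele_counts[[j]])),
                 sort(unname(pan$sites$allele_counts[[j]])))
  }
  expect_identical(pi_gene(back, 400, "per_site")$pi, pan$truth_pi)
})

test_that("plant_paralog_genome answer key follows the strict < 2500 bp rule", {
  g <- plant_paralog_genome(data.frame(chrom = "chr1",
                                       gap_bp = c(1500, 2500, 2499)))
  expect_equal(g$key$is_tandem, c(TRUE, FALSE, TRUE))
  # cross-chromosome pairs are never tandem
  g2 <- plant_paralog_genome(data.frame(chrom = "chr1", chrom_b = "chr2",
                                        gap_bp = 100))
  expect_false(g2$key$is_tandem)
  expect_error(plant_paralog_genome(data.frame(chrom = "chr1", gap_bp = -5)),
               "overlap")
})

test_that("planted genomes re-read from disk reproduce the planted layout", {
  dir <- withr::local_tempdir()
  g <- plant_paralog_genome(data.frame(chrom = c("chr1", "chr1", "chr2"),
                                       gap_bp = c(71, 4963, 300)),
                            dir = dir)
  genes <- read_gff3(g$paths$gff3)
  expect_equal(sort(genes$gene_id), sort(g$genes$gene_id))
  scan <- tandem_scan(genes, read_report(g$paths$relations))
  key <- read_report(g$paths$key)
  expect_equal(scan$is_tandem, key$is_tandem)
  expect_equal(scan$gap_bp, key$gap_bp)
})
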