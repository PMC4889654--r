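test_that("observed heterozygosity counts heterozygote fractions", {
  expect_equal(unname(observed_heterozygosity(
    make_gm(matrix(1L, 4, 6)))$individual), rep(1, 4))
  expect_equal(unname(observed_heterozygosity(
    make_gm(matrix(c(0L, 2L), 4, 6)))$individual), rep(0, 4))
  # 4-sample toy with hand-counted heterozygotes
  g <- rbind(c(1L, 1L, 0L, 2L),   # 2 het of 4
             c(1L, NA, 0L, 0L),   # 1 het of 3
             c(0L, 0L, 0L, 0L),   # 0 het of 4
             c(NA, NA, NA, NA))   # no calls
  ho <- observed_heterozygosity(make_gm(g),
                                popmap = data.frame(
                                  sample = sprintf("s%02d", 1:4),
                                  population = c("P1", "P1", "P2", "P2")))
  expect_equal(unname(ho$individual), c(0.5, 1 / 3, 0, NA))
  expect_equal(unname(ho$population[["P1"]]), mean(c(0.5, 1 / 3)))
  expect_equal(unname(ho$population[["P2"]]), 0)
})

test_that("windowed pi matches the direct formula and the pairwise oracle", {
  # single site, p = 0.5, 10 alleles, 1000-bp window
  g <- matrix(c(0L, 1L, 1L, 1L, 2L), ncol = 1)
  gm <- make_gm(g, pos = 500, contig_lengths = c(ctgA = 1000))
  pi <- nucleotide_diversity(gm, 1000)
  expect_equal(pi$value, (2 * 0.25 * 10 / 9) / 1000, tolerance = 1e-12)
  # empty window -> 0
  gm2 <- make_gm(g, pos = 500, contig_lengths = c(ctgA = 2000))
  pi2 <- nucleotide_diversity(gm2, 1000)
  expect_equal(pi2$value[2], 0)
  # permutation invariance
  perm <- gm_subset(gm, samples = c(3, 1, 5, 2, 4))
  expect_equal(nucleotide_diversity(perm, 1000)$value, pi$value)
  # haplotype-enumeration oracle on random windows
  set.seed(8)
  for (rep in 1:5) {
    haps <- matrix(rbinom(10 * 6, 1, 0.4), nrow = 10)
    geno <- haps[c(1, 3, 5, 7, 9), ] + haps[c(2, 4, 6, 8, 10), ]
    gm3 <- make_gm(geno, pos = seq(50, 550, by = 100),
                   contig_lengths = c(ctgA = 1000))
    got <- nucleotide_diversity(gm3, 1000)$value[1]
    expect_equal(got, oracle_pi(haps, 1000), tolerance = 1e-9)
  }
})

test_that("Tajima's D equals an independent transcription of the formulas", {
  set.seed(9)
  for (rep in 1:8) {
    haps <- matrix(rbinom(10 * 8, 1, 0.35), nrow = 10)
    geno <- haps[c(1, 3, 5, 7, 9), ] + haps[c(2, 4, 6, 8, 10), ]
    gm <- make_gm(geno, pos = seq(50, 750, by = 100),
                  contig_lengths = c(ctgA = 1000))
    got <- tajimas_d(gm, 1000)
    want <- oracle_tajima_d(haps)
    if (is.na(want)) expect_false(got$defined[1])
    else expect_equal(got$value[1], want, tolerance = 1e-9)
  }
})

test_that("Tajima windows without SNPs are undefined and averaged correctly", {
  haps <- matrix(rbinom(10 * 3, 1, 0.5), nrow = 10)
  while (!any(colSums(haps) %in% 1:9))
    haps <- matrix(rbinom(10 * 3, 1, 0.5), nrow = 10)
  geno <- haps[c(1, 3, 5, 7, 9), ] + haps[c(2, 4, 6, 8, 10), ]
  gm <- make_gm(geno, pos = c(100, 200, 300),
                contig_lengths = c(ctgA = 3000))
  td <- tajimas_d(gm, 1000)
  expect_equal(nrow(td), 3)
  expect_false(td$defined[2])
  expect_false(td$defined[3])
  d1 <- td$value[1]
  expect_equal(attr(td, "average_all"), d1 / 3)
  expect_equal(attr(td, "average_snp"), d1)
  # too few sequences is an explicit error
  expect_error(tajimas_d(make_gm(matrix(1L, 1, 3))), "at least 4")
})

test_that("exact HWE p-values match full enumeration", {
  # exact Hardy-Weinberg proportions: the observed configuration is modal
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)
  # (5, 0, 5) vs enumeration over het in {0, 2, ..., 10}
  expect_equal(hwe_exact_test(5, 0, 5), oracle_hwe(5, 0, 5),
               tolerance = 1e-12)
  # assorted counts against the oracle
  for (cnt in list(c(3, 4, 3), c(8, 1, 1), c(0, 10, 0), c(2, 7, 11))) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  # all-heterozygote excess is significant from n = 10 up
  expect_lt(hwe_exact_test(0, 10, 0), 0.05)
  # monomorphic -> p = 1
  expect_equal(hwe_exact_test(10, 0, 0), 1)
})

test_that("HWE flags: p in (0,1], BH set contains the Bonferroni set", {
  set.seed(11)
  g <- matrix(sample(c(0L, 1L, 2L), 30 * 40, replace = TRUE,
                     prob = c(0.45, 0.1, 0.45)), nrow = 30)
  gm <- make_gm(g)
  hw <- hwe_exact(gm)
  expect_true(all(hw$p > 0 & hw$p <= 1))
  expect_true(all(hw$sig_bonf <= hw$sig_bh))  # Bonferroni subset of BH
  expect_true(any(hw$sig_bh))
  # adjusted values agree with the hand step-up / scaling
  expect_equal(hw$p_bh, oracle_bh(hw$p), tolerance = 1e-12)
  expect_equal(hw$p_bonf, pmin(hw$p * nrow(hw), 1), tolerance = 1e-12)
})

test_that("Weir-Cockerham Fst behaves at the analytic anchors", {
  pm <- data.frame(sample = sprintf("s%02d", 1:20),
                   population = rep(c("P1", "P2"), each = 10))
  # identical allele frequencies -> Fst near 0 (slightly negative allowed)
  g_same <- rbind(matrix(rep(c(0L, 1L, 1L, 2L, 0L), 2), 10, 6),
                  matrix(rep(c(0L, 1L, 1L, 2L, 0L), 2), 10, 6))
  f0 <- wc_fst(make_gm(g_same), pm)
  expect_equal(f0$weighted_fst, f0$mean_fst)  # same denominator everywhere
  expect_lt(abs(f0$weighted_fst), 0.15)
  # fixed difference with equal sample sizes -> per-site Fst exactly 1
  g_fix <- matrix(c(rep(0L, 10), rep(2L, 10)), ncol = 1)
  f1 <- wc_fst(make_gm(g_fix), pm)
  expect_equal(f1$per_site$fst, 1, tolerance = 1e-12)
  expect_equal(f1$weighted_fst, 1, tolerance = 1e-12)
  # per-site Fst bounded above by 1
  set.seed(3)
  g_rand <- matrix(sample(0:2, 20 * 50, TRUE), nrow = 20)
  fr <- wc_fst(make_gm(g_rand), pm)
  expect_true(all(fr$per_site$fst <= 1 + 1e-12, na.rm = TRUE))
  # a population with no calls at all is an explicit error
  g_nc <- g_fix; g_nc[11:20, ] <- NA
  expect_error(wc_fst(make_gm(g_nc), pm), "no calls")
  expect_error(wc_fst(make_gm(g_fix), pm, pops = "P1"), "at least two")
})

test_that("pairwise Fst matrix holds mean above and weighted below", {
  set.seed(13)
  cfg <- sim_config(n_populations = 3, n_samples_per_pop = 12,
                    n_contigs = 4, contig_length = 5000, fst_target = 0.15,
                    missing_rate = 0, n_spiked_pairs = 0,
                    n_spiked_diff_sites = 0, seed = 13)
  pan <- simulate_haplotypes(cfg)
  gm <- panel_to_gm(pan)
  pm <- data.frame(sample = pan$sample_ids, population = pan$pop)
  m <- pairwise_fst_matrix(gm, pm)
  expect_equal(diag(m), c(popA = 0, popB = 0, popC = 0))
  f12 <- wc_fst(gm, pm, pops = c("popA", "popB"))
  expect_equal(m["popA", "popB"], f12$mean_fst)
  expect_equal(m["popB", "popA"], f12$weighted_fst)
})

test_that("SNP density counts per full-length window", {
  g <- matrix(c(0L, 1L, 1L, 0L, 2L, 1L), nrow = 3)
  gm <- make_gm(g, pos = c(500, 9000), contig_lengths = c(ctgA = 10000))
  dens <- snp_density(gm, 10000)
  expect_equal(dens$n_snps, 2)
  expect_equal(unname(attr(dens, "summary")["mean"]), 2)
  # finer windows, including empty ones over the full contig
  dens2 <- snp_density(gm, 1000)
  expect_equal(nrow(dens2), 10)
  expect_equal(dens2$n_snps, c(1, rep(0, 7), 1, 0))
})
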