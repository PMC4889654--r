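test_that("the shrink transform is exact, monotone and invertible", {
  expect_equal(scale_r2(0.5, 0.7), 0.5)              # fixed point
  expect_equal(scale_r2(c(0, 1), 0.999), c(0.0005, 0.9995))
  x <- seq(0, 1, by = 0.01)
  y <- scale_r2(x, 0.999)
  expect_true(all(y > 0 & y < 1))
  expect_true(all(diff(y) > 0))                      # order preserving
  expect_equal(unscale_r2(y, 0.999), x, tolerance = 1e-12)
  expect_error(scale_r2(1.2), "\\[0, 1\\]")
  expect_error(scale_r2(-0.1), "\\[0, 1\\]")
  expect_error(scale_r2(0.5, theta = 1), "theta")
  expect_error(scale_r2(0.5, theta = 0), "theta")
})

test_that("Beta fitting recovers known shapes and respects the moments start", {
  set.seed(71)
  x <- rbeta(5000, 2, 8)
  ft <- fit_beta(x)
  expect_true(ft$converged)
  expect_lt(abs(ft$shape_a - 2) / 2, 0.15)
  expect_lt(abs(ft$shape_b - 8) / 8, 0.15)
  # method-of-moments identity: a = m (m(1-m)/v - 1)
  m <- mean(x); v <- var(x)
  a_mom <- m * (m * (1 - m) / v - 1)
  expect_lt(abs(ft$shape_a - a_mom) / a_mom, 0.2)
  # mirrored sample -> symmetric shapes
  xs <- c(x, 1 - x)
  fs <- fit_beta(xs)
  expect_lt(abs(fs$shape_a - fs$shape_b) / fs$shape_a, 0.05)
  # too few values is an error
  expect_error(fit_beta(c(0.2, 0.4)), "at least")
  expect_error(fit_beta(c(rep(0.5, 20), 1)), "strictly")
})

test_that("pair probabilities equal the Beta upper tail and rank monotonically", {
  set.seed(72)
  d <- rep(seq(25, 2000, by = 50), each = 30)
  pairs <- data.frame(contig = "c", pos_a = 1, pos_b = 1 + d, distance = d,
                      r2 = rbeta(length(d), 1.2, 6), n_obs = 50)
  bs <- bin_by_distance(pairs, 50)
  bf <- fit_bin_betas(bs)
  probs <- pair_probabilities(bs, bf)
  # quadrature oracle: p_raw = integral of the fitted density above x
  idx <- seq(1, nrow(probs), length.out = 10)
  for (i in round(idx)) {
    f <- bf$fits[bf$fits$group == probs$group[i], ]
    quad <- integrate(function(z) dbeta(z, f$shape_a, f$shape_b),
                      probs$scaled_r2[i], 1, rel.tol = 1e-10)$value
    expect_equal(probs$p_raw[i], quad, tolerance = 1e-8)
  }
  # a pair sitting at its bin's fitted median has p_raw exactly 0.5
  d_med <- rep(25, 20)
  med_fit <- list(fits = data.frame(group = 1, lo = 0, hi = 50, n = 20,
                                    shape_a = 2, shape_b = 5,
                                    method = "mle", converged = TRUE),
                  pair_group = rep(1L, 20), theta = 0.999)
  med_pairs <- data.frame(contig = "c", pos_a = 1, pos_b = 26,
                          distance = d_med,
                          r2 = unscale_r2(qbeta(0.5, 2, 5), 0.999),
                          n_obs = 50)
  med_bs <- bin_by_distance(med_pairs, 50)
  med_probs <- pair_probabilities(med_bs, med_fit)
  expect_equal(med_probs$p_raw, rep(0.5, 20), tolerance = 1e-12)
  # within each bin the largest value has the smallest p_raw
  for (g in unique(probs$group)) {
    sub <- probs[probs$group == g, ]
    expect_equal(order(sub$r2), order(-sub$p_raw),
                 label = paste("group", g))
  }
})

test_that("bin merging guarantees the minimum occupancy", {
  d <- c(rep(25, 30), rep(75, 3), rep(125, 4), rep(1025, 12), rep(2025, 2))
  pairs <- data.frame(contig = "c", pos_a = 1, pos_b = 1 + d, distance = d,
                      r2 = runif(length(d), 0.05, 0.6), n_obs = 50)
  bs <- bin_by_distance(pairs, 50)
  bf <- fit_bin_betas(bs, min_n = 10)
  cnt <- table(bf$pair_group)
  expect_true(all(cnt >= 10))
  expect_equal(sum(cnt), nrow(pairs))
  # groups cover contiguous, ordered distance ranges
  expect_true(all(diff(bf$fits$lo) > 0))
})

test_that("BH flagging matches the hand step-up and controls the null rate", {
  # hand-checked list: adjusted (0.003, 0.003, 0.5), two flagged at 0.01
  probs <- data.frame(contig = "c", pos_a = 1:3, pos_b = 2:4,
                      distance = 1, r2 = 0.5, n_obs = 50, group = 1,
                      scaled_r2 = 0.5, p_raw = c(0.001, 0.002, 0.5))
  fl <- flag_outliers(probs, alpha = 0.01)
  expect_equal(fl$p_adj, c(0.003, 0.003, 0.5), tolerance = 1e-12)
  expect_equal(fl$flagged, c(TRUE, TRUE, FALSE))
  expect_equal(fl$p_adj, oracle_bh(fl$p_raw), tolerance = 1e-12)
  # p_adj never smaller than p_raw; flags monotone in p_adj
  expect_true(all(fl$p_adj >= fl$p_raw))
  # all p_raw = 1 -> nothing flagged
  probs$p_raw <- 1
  expect_equal(sum(flag_outliers(probs)$flagged), 0)
  # null simulation: pairs drawn from their own bin's Beta -> uniform
  # p_raw, few BH flags, ~1% below the raw 0.01 line
  set.seed(73)
  d <- rep(seq(25, 1975, by = 50), each = 250)
  null_pairs <- data.frame(contig = "c", pos_a = 1, pos_b = 1 + d,
                           distance = d, r2 = rbeta(length(d), 1.5, 7),
                           n_obs = 50)
  scan <- ld_outlier_scan(null_pairs)
  expect_lt(scan$summary[["fraction"]], 0.01)
  expect_lt(abs(mean(scan$pairs$p_raw <= 0.01) - 0.01), 0.005)
  ks <- suppressWarnings(ks.test(scan$pairs$p_raw, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("per-bin BH scope adjusts within groups only", {
  probs <- data.frame(contig = "c", pos_a = 1:4, pos_b = 2:5,
                      distance = 1, r2 = 0.5, n_obs = 50,
                      group = c(1, 1, 2, 2), scaled_r2 = 0.5,
                      p_raw = c(0.004, 0.8, 0.004, 0.9))
  fl <- flag_outliers(probs, alpha = 0.01, scope = "bin")
  expect_equal(fl$p_adj, c(0.008, 0.8, 0.008, 0.9), tolerance = 1e-12)
  expect_equal(sum(fl$flagged), 2)
})

test_that("planted high-LD pairs are flagged against a decaying background", {
  cfg <- sim_config(n_populations = 1, n_samples_per_pop = 100,
                    n_contigs = 10, contig_length = 8000,
                    retention_per_bp = 0.999, fst_target = 0,
                    missing_rate = 0, n_spiked_pairs = 3,
                    n_spiked_diff_sites = 0, seed = 55)
  pan <- simulate_haplotypes(cfg)
  scan <- ld_outlier_scan(pairwise_r2(panel_to_gm(pan)))
  key <- with(scan$pairs, paste(contig, pos_a, pos_b))
  flagged <- key[scan$pairs$flagged]
  hits <- with(pan$spiked_pairs, paste(contig, pos_a, pos_b)) %in% flagged
  expect_gte(mean(hits), 0.9)
})
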