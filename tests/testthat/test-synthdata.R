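test_that("LD panel generator is deterministic and matches its LD contract", {
  p1 <- simulate_ld_panel(400, c(5, 3, 1), within_block_corr = 0.5, seed = 11)
  p2 <- simulate_ld_panel(400, c(5, 3, 1), within_block_corr = 0.5, seed = 11)
  expect_identical(p1$G, p2$G)
  expect_true(pleioscan:::validate_ld_panel(p1))

  # independent variants: off-diagonal correlations average ~ 0
  p0 <- simulate_ld_panel(4000, rep(1, 40), within_block_corr = 0, seed = 2)
  off <- p0$R[upper.tri(p0$R)]
  expect_lt(abs(mean(off)), 3 / sqrt(4000))

  # a tightly linked pair reaches the requested LD
  p99 <- simulate_ld_panel(10000, 2, within_block_corr = 0.99, seed = 5)
  expect_gt(cor(p99$G[, 1], p99$G[, 2])^2, 0.9)

  expect_error(simulate_ld_panel(0, c(2)), "n_individuals")
  expect_error(simulate_ld_panel(10, integer(0)), "block_sizes")
  expect_error(simulate_ld_panel(10, c(2), maf_range = c(0, 0.6)), "maf_range")
})

test_that("trait pairs honour target h2 and genetic correlation", {
  p <- simulate_ld_panel(4000, rep(1, 300), within_block_corr = 0, seed = 7,
                         store_R = FALSE)
  # independent traits: genetic values uncorrelated at the 3/sqrt(n) level
  tp0 <- simulate_trait_pair(p, 0.5, 0.5, 0, n_causal = 100,
                             shared_fraction = 0, seed = 3)
  expect_lt(abs(cor(tp0$g1, tp0$g2)), 3 / sqrt(4000))
  expect_equal(var(tp0$g1), 0.5, tolerance = 1e-10)

  # realized genetic correlation unbiased for the target (moment matching)
  rs <- vapply(1:60, function(s)
    simulate_trait_pair(p, 0.5, 0.5, -0.3, n_causal = 150,
                        shared_fraction = 1, seed = 100 + s)$truth$rho_g_realized,
    0)
  expect_lt(abs(mean(rs) + 0.3), 2 * sd(rs) / sqrt(length(rs)) + 0.02)

  # infeasible correlation rejected
  expect_error(simulate_trait_pair(p, 0.5, 0.5, 0.8, 10, shared_fraction = 0.5),
               "infeasible")
  expect_error(simulate_trait_pair(p, 0, 0.5, 0.3, 10), "infeasible")

  # h2 = 0: phenotype is pure noise, marginal z are standard normal
  tpn <- simulate_trait_pair(p, 0, 0, 0, n_causal = 50, seed = 5)
  zz <- compute_marginal_stats(p, tpn$y1)$z
  expect_gt(ks.test(zz, "pnorm")$p.value, 0.01)
})

test_that("cis expression simulation respects window, h2 and degenerate cases", {
  p <- simulate_ld_panel(500, rep(5, 30), within_block_corr = 0.5, seed = 4)
  # h2 = 1, single causal: expression collinear with the dosage column
  e1 <- simulate_cis_expression(p, gene_tss = p$pos[40], h2_cis = 1,
                                causal_ids = 40, seed = 1)
  expect_gt(abs(cor(e1$expression, p$G[, 40])), 1 - 1e-12)

  # causal outside the window is rejected
  expect_error(
    simulate_cis_expression(p, gene_tss = p$pos[1], cis_window = 10000,
                            h2_cis = 0.3, causal_ids = 100),
    "outside the cis window")

  # empty causal set: standard normal expression, independent of dosages
  e0 <- simulate_cis_expression(p, gene_tss = p$pos[40], h2_cis = 0.3,
                                causal_ids = character(), seed = 2)
  expect_equal(mean(e0$expression), 0, tolerance = 1e-10)
  expect_equal(sd(e0$expression), 1, tolerance = 1e-10)

  # h2_cis recovery: regression R2 of expression on the causal dosage
  r2 <- vapply(1:50, function(s) {
    e <- simulate_cis_expression(p, gene_tss = p$pos[40], h2_cis = 0.3,
                                 causal_ids = 40, seed = 10 + s)
    summary(lm(e$expression ~ p$G[, 40]))$r.squared
  }, 0)
  expect_lt(abs(mean(r2) - 0.3), 0.1)
})

test_that("marginal statistics equal per-variant OLS and behave under the null", {
  p <- simulate_ld_panel(300, rep(4, 10), within_block_corr = 0.5, seed = 8)
  set.seed(1)
  y <- rnorm(300) + 0.3 * p$G[, 7]
  ss <- compute_marginal_stats(p, y)
  pleioscan:::validate_summary_stats(ss)
  # brute-force oracle: per-variant simple regression on standardized data
  ys <- as.numeric(scale(y))
  for (j in c(1, 7, 23, 40)) {
    xs <- as.numeric(scale(p$G[, j]))
    fit <- lm(ys ~ xs)
    expect_equal(ss$beta[j], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(ss$se[j], summary(fit)$coefficients[2, 2], tolerance = 1e-8)
  }
  # y equal to a standardized dosage: beta 1, huge z
  ss1 <- compute_marginal_stats(p, as.numeric(scale(p$G[, 5])))
  expect_equal(ss1$beta[5], 1, tolerance = 1e-10)
  expect_gt(abs(ss1$z[5]), 1e6)
  # permuted phenotype: z consistent with N(0, 1)
  set.seed(2)
  ssp <- compute_marginal_stats(p, sample(y))
  expect_gt(ks.test(ssp$z, "pnorm")$p.value, 0.01)
  # requested filters are honoured
  ssf <- compute_marginal_stats(p, y, info = 0.97, maf_min = 0.2,
                                info_min = 0.95)
  expect_true(all(ssf$maf >= 0.2) && all(ssf$info >= 0.95))
})

test_that("peak simulation embeds scorable sites and is reproducible", {
  pw <- accessibility_example_pwm()
  pk1 <- simulate_peaks(30, peak_length = 80, embedded_pwm = pw,
                        embed_prob = 1, seed = 3)
  pk2 <- simulate_peaks(30, peak_length = 80, embedded_pwm = pw,
                        embed_prob = 1, seed = 3)
  expect_identical(pk1$sequences, pk2$sequences)
  expect_true(all(pk1$truth$embedded))
  expect_true(all(pk1$bed$end - pk1$bed$start == 80))

  # every embedded site scores above the 90th percentile of background
  # best-scan scores
  scan_best <- function(s, w = pw$width) {
    n <- nchar(s)
    max(vapply(1:(n - w + 1), function(i) {
      win <- substr(s, i, i + w - 1)
      max(score_window(win, pw),
          score_window(pleioscan:::revcomp(win), pw), na.rm = TRUE)
    }, 0))
  }
  bg <- simulate_peaks(60, peak_length = 80, embedded_pwm = NULL, seed = 4)
  thr <- quantile(vapply(bg$sequences, scan_best, 0), 0.9)
  expect_gte(mean(vapply(pk1$sequences, scan_best, 0) > thr), 0.9)
  # the recorded site is really present at the recorded offset
  expect_true(all(substr(pk1$sequences, pk1$truth$site_start,
                         pk1$truth$site_start + pw$width - 1) ==
                  pk1$truth$site_seq))

  # embed_prob = 0: no site recorded
  pk0 <- simulate_peaks(10, peak_length = 40, embedded_pwm = pw,
                        embed_prob = 0, seed = 5)
  expect_false(any(pk0$truth$embedded))
  expect_error(simulate_peaks(5, peak_length = 5, embedded_pwm = pw),
               "motif width")
})
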