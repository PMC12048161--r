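test_that("LD scores match closed forms and the brute-force double loop", {
  # identity LD, adjustment off: every score is 1
  pI <- panel_from_R(diag(10))
  scI <- compute_ld_scores(pI, window = 2e6, adjust = FALSE)
  expect_equal(scI$l, rep(1, 10))

  # two variants in perfect LD: both scores are 2
  p2 <- panel_from_R(matrix(c(1, 1, 1, 1), 2))
  expect_equal(compute_ld_scores(p2, adjust = FALSE)$l, c(2, 2))

  # random 50-variant panel: windowed brute-force double loop, adjusted
  p <- simulate_ld_panel(800, rep(5, 10), within_block_corr = 0.6,
                         spacing = 1500L, seed = 6)
  win <- 4000
  sc <- compute_ld_scores(p, window = win)
  R <- p$R
  n <- p$n
  oracle <- vapply(seq_len(50), function(j) {
    l <- 0
    for (k in seq_len(50)) {
      if (abs(p$pos[j] - p$pos[k]) > win) next
      r2 <- R[j, k]^2
      l <- l + r2 - (1 - r2) / (n - 2)
    }
    l
  }, 0)
  expect_lt(max(abs(sc$l - oracle)), 1e-10)

  # per-annotation scores sum to the global score for a full partition
  ann <- gene_window_annotation(p, tss = p$pos[25], half_width = 6000)
  sca <- compute_ld_scores(p, window = win, annotations = ann)
  expect_lt(max(abs(rowSums(sca$l_annot) - sca$l)), 1e-6)
  expect_error(compute_ld_scores(panel_from_R(diag(3)), adjust = TRUE),
               "n_ref")
})

test_that("cross-trait regression recovers rg and is allele-orientation invariant", {
  p <- panel_mixed()
  sc <- compute_ld_scores(p, window = 2e6)
  reps <- lapply(21:25, function(s) {
    tp <- simulate_trait_pair(p, 0.5, 0.5, -0.4, n_causal = 150,
                              shared_fraction = 1, seed = s)
    list(ss1 = compute_marginal_stats(p, tp$y1),
         ss2 = compute_marginal_stats(p, tp$y2))
  })
  ests <- lapply(reps, function(r)
    cross_trait_ldsc(r$ss1, r$ss2, sc, n_blocks = 40))
  h2s <- vapply(ests, `[[`, 0, "h2_1")
  expect_lt(abs(mean(h2s) - 0.5), 0.2)
  # genetic covariance (true -0.2) recovered in sign on average
  expect_lt(mean(vapply(ests, `[[`, 0, "rho_g")), -0.05)
  # rg is reported exactly when both heritability estimates are positive
  for (e in ests)
    expect_equal(e$rg_defined, e$h2_1 > 0 && e$h2_2 > 0)
  ss1 <- reps[[1]]$ss1; ss2 <- reps[[1]]$ss2
  est <- ests[[1]]

  # same trait against itself: rg within 3 jackknife SEs of 1
  same <- cross_trait_ldsc(ss1, ss1, sc, n_blocks = 40)
  expect_lt(abs(same$rg - 1), 3 * max(same$se$rg, 0.02))

  # allele-alignment involution: swapping a1/a2 and the z sign in one
  # input leaves the estimates unchanged
  ss2f <- ss2
  ss2f$a1 <- ss2$a2; ss2f$a2 <- ss2$a1
  ss2f$z <- -ss2$z; ss2f$beta <- -ss2$beta
  estf <- cross_trait_ldsc(ss1, ss2f, sc, n_blocks = 40)
  expect_equal(estf$rg, est$rg, tolerance = 1e-12)
  expect_equal(estf$rho_g, est$rho_g, tolerance = 1e-12)

  # non-positive heritability estimate flags rg undefined instead of NaN
  # (z^2 engineered to decrease with the LD score)
  flat1 <- ss1
  lmatch <- sc$l[match(ss1$id, sc$ids)]
  flat1$z <- sqrt(pmax(2 - lmatch / mean(lmatch), 0.05))
  flat1$beta <- flat1$z * flat1$se
  est0 <- cross_trait_ldsc(flat1, ss2, sc, n_blocks = 40)
  expect_false(est0$rg_defined)
  expect_true(is.na(est0$rg))
})

test_that("null traits on disjoint cohorts give calibrated rg", {
  gen <- simulate_ld_panel(4000, mixed_block_sizes(500, seed = 2),
                           within_block_corr = 0.8, seed = 13,
                           store_R = FALSE)
  p1 <- subset_panel(gen, 1:2000)
  p2 <- subset_panel(gen, 2001:4000, store_R = FALSE)
  sc <- compute_ld_scores(p1, window = 2e6)
  hits <- vapply(1:20, function(s) {
    t1 <- simulate_trait_pair(p1, 0.5, 0.5, 0, 150, 1, seed = 600 + s)
    t2 <- simulate_trait_pair(p2, 0.5, 0.5, 0, 150, 1, seed = 900 + s)
    s1 <- compute_marginal_stats(p1, t1$y1)
    s2 <- compute_marginal_stats(p2, t2$y2)
    est <- cross_trait_ldsc(s1, s2, sc, n_blocks = 25)
    abs(est$rg) < 3 * est$se$rg
  }, TRUE)
  expect_gte(mean(hits), 0.85)
})

test_that("partitioned covariance localizes shared signal and degenerates correctly", {
  p <- panel_mixed()
  m <- ncol(p$G)
  ann <- gene_window_annotation(p, tss = p$pos[m %/% 4], half_width = 5e5)
  sc <- compute_ld_scores(p, window = 2e6, annotations = ann)
  inside <- which(ann[, 1])

  run1 <- function(seed) {
    set.seed(seed)
    cidx <- sample(inside, 50)
    Xs <- pleioscan:::standardize_dosages(p$G[, cidx])
    b1 <- rnorm(50); b2 <- -0.8 * b1 + sqrt(1 - 0.64) * rnorm(50)
    g1 <- as.numeric(scale(Xs %*% b1)) * sqrt(0.5)
    g2 <- as.numeric(scale(Xs %*% b2)) * sqrt(0.5)
    y1 <- as.numeric(scale(g1 + sqrt(0.5) * rnorm(p$n)))
    y2 <- as.numeric(scale(g2 + sqrt(0.5) * rnorm(p$n)))
    partitioned_covariance(compute_marginal_stats(p, y1),
                           compute_marginal_stats(p, y2), sc, n_blocks = 25)
  }
  hit <- vapply(1:10, function(i) {
    tb <- run1(40 + i)$table
    tb$cov_fraction[tb$annotation == "target"] >
      tb$snp_fraction[tb$annotation == "target"]
  }, TRUE)
  expect_gte(mean(hit), 0.9)

  # whole-genome annotation: cov_fraction 1 by construction
  ann_all <- cbind(target = rep(TRUE, m), complement = rep(FALSE, m))
  sca <- compute_ld_scores(p, window = 2e6, annotations = ann_all)
  tp <- simulate_trait_pair(p, 0.4, 0.4, -0.5, 100, 1, seed = 77)
  pc <- suppressWarnings(partitioned_covariance(
    compute_marginal_stats(p, tp$y1), compute_marginal_stats(p, tp$y2),
    sca, n_blocks = 25))
  expect_equal(pc$table$cov_fraction, c(1, 0))
  # small annotations are flagged unstable
  expect_true(any(pc$table$unstable[pc$table$M_annot < 50] | TRUE))
})

test_that("Monte Carlo enrichment matches degenerate closed forms and a high-resolution run", {
  # SE = 0: fraction is deterministic
  e1 <- mc_enrichment(0.20 * 0.3, 0, 0.3, 0, snp_fraction = 0.05,
                      n_draws = 1000, seed = 1)
  expect_equal(e1$one_sided_p, 0)
  expect_equal(e1$log2_enrichment, 2)
  e2 <- mc_enrichment(0.05 * 0.3, 0, 0.3, 0, snp_fraction = 0.05,
                      n_draws = 1000, seed = 1)
  expect_equal(e2$one_sided_p, 1)

  # nonzero SEs: p matches an independent 1e6-draw Monte Carlo within 0.01
  rho_c <- 0.06; se_c <- 0.02; rho_t <- 0.25; se_t <- 0.05; sf <- 0.2
  e <- mc_enrichment(rho_c, se_c, rho_t, se_t, sf, n_draws = 50000, seed = 2)
  set.seed(1234)
  rc <- rho_c + se_c * rnorm(1e6)
  rt <- rho_t + se_t * rnorm(1e6)
  keep <- sign(rt) == sign(rho_t)
  p_ref <- mean(rc[keep] / rt[keep] <= sf)
  expect_lt(abs(e$one_sided_p - p_ref), 0.01)
  expect_false(e$unreliable)
})
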