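test_that("single-effect decomposition isolates clean signals and stays silent on null data", {
  z <- rep(0, 20); z[7] <- 10
  fit <- finemap_locus(z, diag(20), n = 10000)
  expect_equal(length(fit$cs), 1L)
  expect_equal(fit$cs[[1]], 7L)
  expect_equal(sum(fit$alpha[1, ]), 1, tolerance = 1e-6)
  expect_true(all(abs(rowSums(fit$alpha) - 1) < 1e-6))

  fit0 <- finemap_locus(rep(0, 20), diag(20), n = 10000)
  expect_equal(length(fit0$cs), 0L)

  expect_error(finemap_locus(rep(0, 5), diag(4), n = 100), "dimensions")
  expect_error(finemap_locus(c(1, NA, 0), diag(3), n = 100), "finite")
})

test_that("two causal variants in separate LD blocks are each captured", {
  hits <- vapply(1:10, function(s) {
    p <- simulate_ld_panel(8000, rep(10, 5), within_block_corr = 0.7,
                           seed = 200 + s, store_R = TRUE)
    set.seed(s)
    y <- sqrt(0.005) * scale(p$G[, 13]) + sqrt(0.005) * scale(p$G[, 37]) +
      rnorm(8000)
    ss <- compute_marginal_stats(p, y)
    fit <- finemap_locus(ss$z, p$R, 8000)
    any(vapply(fit$cs, function(cset) 13 %in% cset, TRUE)) &&
      any(vapply(fit$cs, function(cset) 37 %in% cset, TRUE))
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("credible sets are the smallest descending-posterior prefix at the target coverage", {
  p <- simulate_ld_panel(6000, rep(8, 4), within_block_corr = 0.85, seed = 31)
  set.seed(31)
  y <- sqrt(0.006) * scale(p$G[, 12]) + rnorm(6000)
  ss <- compute_marginal_stats(p, y)
  fit <- finemap_locus(ss$z, p$R, 6000, coverage = 0.95)
  expect_gte(length(fit$cs), 1L)
  for (i in seq_along(fit$cs)) {
    l <- fit$cs_effect[i]
    a <- fit$alpha[l, ]
    ord <- order(a, decreasing = TRUE)
    k <- length(fit$cs[[i]])
    expect_gte(sum(a[fit$cs[[i]]]), 0.95)
    expect_setequal(fit$cs[[i]], ord[seq_len(k)])
    if (k > 1) expect_lt(sum(a[ord[seq_len(k - 1)]]), 0.95)
    expect_gte(fit$cs_purity[i], 0.5)
  }
})

test_that("pairwise colocalization equals brute-force configuration enumeration", {
  lbf1 <- c(2.5, 0.3, -1.0)
  lbf2 <- c(1.8, 2.2, 0.1)
  p1 <- 1e-4; p2 <- 1e-4; p12 <- 1e-5
  cc <- coloc_pair(lbf1, lbf2, p1, p2, p12)
  # enumeration over causal-variant configurations
  bf1 <- exp(lbf1); bf2 <- exp(lbf2)
  L0 <- 1
  L1 <- p1 * sum(bf1)
  L2 <- p2 * sum(bf2)
  L3 <- p1 * p2 * sum(outer(bf1, bf2)[!diag(3)])
  L4 <- p12 * sum(bf1 * bf2)
  post <- c(L0, L1, L2, L3, L4) / sum(L0, L1, L2, L3, L4)
  expect_equal(as.numeric(cc[1, c("pph0", "pph1", "pph2", "pph3", "pph4")]),
               post, tolerance = 1e-8)
  expect_equal(sum(cc[1, c("pph0", "pph1", "pph2", "pph3", "pph4")]), 1,
               tolerance = 1e-6)

  # multiplying both traits' Bayes factors by constants leaves the
  # colocalization decision unchanged
  cc2 <- coloc_pair(lbf1 + log(50), lbf2 + log(3), p1, p2, p12)
  expect_equal(cc2$colocalized, cc$colocalized)
  expect_equal(cc2$pph4 / cc2$pph3, cc$pph4 / cc$pph3, tolerance = 1e-6)
})

test_that("shared and distinct causal variants are separated by the PPH4/PPH3 rule", {
  # identical z vectors with one strong peak: overwhelming H4
  z <- rep(0, 15); z[4] <- 9
  f1 <- finemap_locus(z, diag(15), n = 5000)
  cc <- coloc_pair(f1, f1)
  expect_gt(cc$pph4[1], 0.99)

  # strong signals at two uncorrelated variants: H3 wins
  za <- rep(0, 15); za[3] <- 9
  zb <- rep(0, 15); zb[12] <- 9
  fa <- finemap_locus(za, diag(15), n = 5000)
  fb <- finemap_locus(zb, diag(15), n = 5000)
  cc2 <- coloc_pair(fa, fb)
  expect_gt(cc2$pph3[1], cc2$pph4[1])
  # empty effect list: empty result
  f0 <- finemap_locus(rep(0, 15), diag(15), n = 5000)
  expect_equal(nrow(coloc_pair(f0, f1)), 0L)
})

test_that("trait network pruning, edges and cliques match an independent enumeration", {
  edge <- function(n1, n2, c1, c2, pph4, pph3 = 0.1)
    data.frame(node1 = n1, node2 = n2, class1 = c1, class2 = c2,
               pph3 = pph3, pph4 = pph4)
  # three pairwise colocalized signals: one clique
  e3 <- rbind(edge("gX", "bmi", "expression", "focal", 0.9),
              edge("gX", "t1", "expression", "endo", 0.85),
              edge("bmi", "t1", "focal", "endo", 0.8))
  net <- build_network(e3)
  expect_equal(nrow(net$cliques), 1L)
  expect_equal(nrow(net$weak_trios), 0L)
  # drop one edge: weak trio, no clique
  e2 <- e3; e2$pph4[3] <- 0.01
  net2 <- build_network(e2)
  expect_equal(nrow(net2$cliques), 0L)
  expect_equal(nrow(net2$weak_trios), 1L)

  # near-duplicate endophenotypes collapse to a representative
  rg <- matrix(0.95, 2, 2, dimnames = list(c("t1", "t2"), c("t1", "t2")))
  diag(rg) <- 1
  e4 <- rbind(e3, edge("gX", "t2", "expression", "endo", 0.9),
              edge("bmi", "t2", "focal", "endo", 0.88))
  net4 <- build_network(e4, rg = rg,
                        categories = c(t1 = "vol", t2 = "vol"))
  endo_nodes <- net4$nodes[net4$nodes$class == "endo", ]
  expect_equal(nrow(endo_nodes), 1L)
  expect_equal(endo_nodes$size, 2L)

  # random edge sets: cliques equal igraph triangle enumeration
  skip_if_not_installed("igraph")
  set.seed(8)
  for (rep in 1:5) {
    expr_n <- paste0("g", 1:3); focal_n <- "bmi"; endo_n <- paste0("t", 1:3)
    rows <- list()
    for (a in expr_n) for (b in focal_n)
      rows[[length(rows) + 1]] <- edge(a, b, "expression", "focal",
                                       runif(1))
    for (a in expr_n) for (b in endo_n)
      rows[[length(rows) + 1]] <- edge(a, b, "expression", "endo", runif(1))
    for (a in focal_n) for (b in endo_n)
      rows[[length(rows) + 1]] <- edge(a, b, "focal", "endo", runif(1))
    edges <- do.call(rbind, rows)
    net <- build_network(edges)
    kept <- net$edges[net$edges$colocalized, c("node1", "node2")]
    g <- igraph::graph_from_data_frame(kept, directed = FALSE)
    tri <- igraph::triangles(g)
    n_tri <- length(tri) / 3
    # all nodes are in distinct classes, so every triangle is tripartite
    expect_equal(nrow(net$cliques), n_tri)
  }
})

test_that("credible-set intersection finds the shared causal variant and demotes failures", {
  hits <- vapply(1:10, function(s) {
    gen <- simulate_ld_panel(9000, rep(8, 5), within_block_corr = 0.7,
                             seed = 300 + s, store_R = FALSE)
    ep <- subset_panel(gen, 1:1000)
    gp <- subset_panel(gen, 1001:9000)
    cv <- 20
    ex <- simulate_cis_expression(ep, gene_tss = ep$pos[cv], h2_cis = 0.4,
                                  causal_ids = cv, seed = s)
    set.seed(s)
    xs <- as.numeric(scale(gp$G[, cv]))
    y1 <- sqrt(0.008) * xs + sqrt(0.992) * rnorm(8000)
    y2 <- -sqrt(0.008) * xs + sqrt(0.992) * rnorm(8000)
    se <- compute_marginal_stats(ep, ex$expression)
    s1 <- compute_marginal_stats(gp, y1)
    s2 <- compute_marginal_stats(gp, y2)
    fe <- finemap_locus(se$z, ep$R, 1000, variant_ids = se$id)
    ff <- finemap_locus(s1$z, gp$R, 8000, variant_ids = s1$id)
    fn <- finemap_locus(s2$z, gp$R, 8000, variant_ids = s2$id)
    ci <- intersect_credible_sets(fe, ff, fn, gp,
                                  2 * pnorm(-abs(s1$z)))
    !ci$demoted && gp$variant_ids[cv] %in% ci$table$id
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  # identical sets intersect to themselves; disjoint sets demote
  z <- rep(0, 12); z[5] <- 10
  f <- finemap_locus(z, diag(12), n = 4000)
  pn <- panel_from_R(diag(12))
  ci <- intersect_credible_sets(f, f, f, pn, rep(1e-10, 12))
  expect_false(ci$demoted)
  expect_equal(nrow(ci$table), 1L)
  expect_true(ci$table$is_lead[1])
  z2 <- rep(0, 12); z2[9] <- 10
  f2 <- finemap_locus(z2, diag(12), n = 4000)
  ci2 <- intersect_credible_sets(f, f, f2, pn, rep(1e-10, 12))
  expect_true(ci2$demoted)
})
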