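test_that("SMR statistic and p-value match the closed form on a grid", {
  for (ze in c(-8, -4.5, 5, 6, 12)) for (zg in c(-6, -1.2, 0, 2.5, 9)) {
    be <- 0.5; bg <- 0.02
    s <- smr_test(ze, zg, be, bg)
    T_ref <- (zg^2 * ze^2) / (zg^2 + ze^2)
    expect_equal(s$T_smr, T_ref, tolerance = 1e-12)
    expect_equal(s$b_smr, bg / be, tolerance = 1e-12)
    # independent 1-df chi-square upper tail via the normal CDF
    expect_equal(s$p_smr, 2 * pnorm(-sqrt(T_ref)), tolerance = 1e-10)
    if (T_ref > 0)
      expect_equal(s$se_smr, abs(bg / be) / sqrt(T_ref), tolerance = 1e-12)
  }
  # z_gwas = 0: no evidence
  s0 <- smr_test(6, 0, 0.5, 0)
  expect_equal(s0$T_smr, 0); expect_equal(s0$p_smr, 1)
  # z_eqtl -> infinity: T -> z_gwas^2
  expect_equal(smr_test(1e9, 4, 1, 0.1)$T_smr, 16, tolerance = 1e-8)
  expect_error(smr_test(0, 4, 0, 0.1), "instrument")
})

test_that("SMR p-values are uniform under the null", {
  sc <- smr_scenario(501, n_eqtl = 400, n_gwas = 400, h2_cis = 0.4,
                     h2_trait = 0.01, block_sizes = rep(5, 8))
  inst <- select_instrument(sc$eqtl, 5e-8)
  expect_false(is.na(inst))
  ei <- sc$eqtl[sc$eqtl$id == inst, ]
  set.seed(7)
  ps <- vapply(1:500, function(i) {
    gz <- compute_marginal_stats(sc$gwas_panel, sample(sc$y))
    gi <- gz[gz$id == inst, ]
    smr_test(ei$z, gi$z, ei$beta, gi$beta)$p_smr
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the approximate PPA is monotone and matches the ABF formula", {
  # worked cases against an independent (non-log) evaluation
  for (case in list(c(T = 4, se = 0.3), c(T = 16, se = 0.05),
                    c(T = 36, se = 0.12))) {
    V <- case["se"]^2; W <- 0.15^2; pi0 <- 0.01
    abf <- sqrt(V / (V + W)) * exp(W * case["T"] / (2 * (V + W)))
    ppa_ref <- abf * pi0 / (abf * pi0 + 1 - pi0)
    expect_equal(ppa_from_smr(case["T"], case["se"]),
                 unname(ppa_ref), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_lt(ppa_from_smr(0, 0.2), 0.01)                      # below the prior
  expect_gt(ppa_from_smr(25, 0.2), ppa_from_smr(9, 0.2))     # monotone in T
  # extremely strong evidence saturates at 1 without overflow
  expect_equal(ppa_from_smr(5000, 0.1), 1, tolerance = 1e-12)
  expect_error(ppa_from_smr(4, 0.1, prior_pi = 1.2), "prior_pi")
})

test_that("instrument selection takes the top significant eQTL with a positional tie-break", {
  ss <- data.frame(id = c("a", "b", "c"), chrom = "1",
                   pos = c(100, 200, 300), a1 = "A", a2 = "G",
                   beta = c(0.1, 1, 0.1), se = 0.1,
                   z = c(1, 10, 1), n = 500, maf = 0.3, info = 1)
  expect_equal(select_instrument(ss), "b")
  # all below threshold: none
  ss2 <- ss; ss2$z <- c(1, 2, 1)
  expect_true(is.na(select_instrument(ss2)))
  # |z| tie: smallest position wins
  ss3 <- ss; ss3$z <- c(10, -10, 3)
  expect_equal(select_instrument(ss3), "a")
  expect_true(is.na(suppressMessages(select_instrument(ss[0, ]))))
})

test_that("SMR is sign-symmetric in the eQTL allele orientation", {
  s1 <- smr_test(6, 4, 0.5, 0.02)
  s2 <- smr_test(-6, 4, -0.5, 0.02)
  expect_equal(s2$b_smr, -s1$b_smr)
  expect_equal(s2$T_smr, s1$T_smr)
  expect_equal(s2$p_smr, s1$p_smr)
  expect_equal(ppa_from_smr(s2$T_smr, s2$se_smr),
               ppa_from_smr(s1$T_smr, s1$se_smr))
})

test_that("HEIDI distinguishes shared from linked causal variants", {
  # shared causal variant: heterogeneity should not be detected
  sh <- smr_scenario(701)
  inst <- select_instrument(sh$eqtl)
  h <- heidi_test(sh$eqtl, sh$gwas, sh$eqtl_panel, inst)
  expect_false(h$untested)
  expect_gt(h$p_heidi, 0.05)

  # linkage (distinct causal variants in LD): strong heterogeneity at
  # large GWAS n
  li <- smr_scenario(702, n_gwas = 20000, trait_idx = 36, corr = 0.7)
  insl <- select_instrument(li$eqtl)
  hl <- heidi_test(li$eqtl, li$gwas, li$eqtl_panel, insl)
  expect_lt(hl$p_heidi, 0.05)

  # rescaling all GWAS betas by a positive constant leaves HEIDI unchanged
  gws <- li$gwas
  gws$beta <- 3 * gws$beta; gws$se <- 3 * gws$se
  hs <- heidi_test(li$eqtl, gws, li$eqtl_panel, insl)
  expect_equal(hs$p_heidi, hl$p_heidi, tolerance = 1e-10)

  # no eligible companions: untested, passes by default in run_smr
  tiny <- subset_panel(sh$eqtl_panel, variants = 31:35)
  et <- sh$eqtl[sh$eqtl$id %in% tiny$variant_ids, ]
  et$z[et$id != inst] <- 0.1
  et$beta[et$id != inst] <- 0.001
  ht <- heidi_test(et, sh$gwas, tiny, inst)
  expect_true(ht$untested)
  expect_true(is.na(ht$p_heidi))
})

test_that("pleiotropic gene discovery requires both the focal trait and an endophenotype", {
  row <- function(gene, trait, ppa, ph, pass) {
    data.frame(gene = gene, tissue = "t1", trait = trait, instrument = "v",
               b_smr = 0.1, se_smr = 0.05, T_smr = 9, p_smr = 1e-3,
               ppa = ppa, p_heidi = ph, n_heidi_snps = 5,
               heidi_untested = FALSE, pass = pass)
  }
  res <- rbind(
    row("g1", "focal", 0.9, 0.5, TRUE), row("g1", "endoA", 0.8, 0.4, TRUE),
    row("g2", "focal", 0.9, 0.5, TRUE),                     # focal only
    row("g3", "endoA", 0.95, 0.5, TRUE),                    # endo only
    row("g4", "focal", 0.7, 0.01, FALSE), row("g4", "endoA", 0.9, 0.5, TRUE))
  out <- discover_pleiotropic_genes(res, "focal")
  expect_equal(out$gene, "g1")
  expect_equal(out$endo_trait, "endoA")
  expect_equal(nrow(discover_pleiotropic_genes(res[0, ], "focal")), 0)
})

test_that("run_smr discovers a shared-causal gene end to end", {
  sc <- smr_scenario(703)
  r <- run_smr(sc$eqtl, sc$gwas, sc$eqtl_panel, gene = "g", trait = "focal")
  expect_s3_class(r, "smr_result")
  expect_gt(r$ppa, 0.5)
  expect_true(r$pass)
})
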