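# shared fixtures, built once per test run
.fx <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, fn(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# medium panel with heterogeneous LD blocks (the LDSC tests need LD-score
# variation across variants)
mixed_block_sizes <- function(total, sizes = c(1, 2, 5, 10, 20), seed = 9) {
  set.seed(seed)
  bs <- sample(rep(sizes, ceiling(total / sum(sizes)) + 1))
  bs <- bs[cumsum(bs) <= total]
  c(bs, rep(1L, total - sum(bs)))
}

panel_mixed <- function() fixture("panel_mixed", function() {
  simulate_ld_panel(4000, mixed_block_sizes(600), within_block_corr = 0.8,
                    seed = 3)
})

# an ld_panel built from an explicit correlation matrix (no genotypes)
panel_from_R <- function(R, spacing = 1000L) {
  m <- nrow(R)
  structure(list(
    variant_ids = paste0("v", seq_len(m)),
    chrom = rep("1", m),
    pos = seq_len(m) * spacing,
    a1 = rep("A", m), a2 = rep("G", m),
    maf = rep(0.3, m), G = NULL, R = R, n = NULL
  ), class = "ld_panel")
}

# eQTL cohort + GWAS cohort drawn from one genome (shared variant map),
# with a single causal variant driving expression and, at `trait_idx`,
# the trait; used by the SMR / HEIDI / coloc tests
smr_scenario <- function(seed, n_eqtl = 700, n_gwas = 3800, expr_idx = 35,
                         trait_idx = 35, h2_cis = 0.3, h2_trait = 0.01,
                         block_sizes = rep(10, 8), corr = 0.6) {
  gen <- simulate_ld_panel(n_eqtl + n_gwas, block_sizes,
                           within_block_corr = corr, seed = seed)
  ep <- subset_panel(gen, seq_len(n_eqtl))
  gp <- subset_panel(gen, n_eqtl + seq_len(n_gwas), store_R = FALSE)
  ex <- simulate_cis_expression(ep, gene_tss = ep$pos[expr_idx],
                                h2_cis = h2_cis, causal_ids = expr_idx,
                                seed = seed + 1)
  set.seed(seed + 2)
  xs <- as.numeric(scale(gp$G[, trait_idx]))
  y <- sqrt(h2_trait) * xs + sqrt(1 - h2_trait) * stats::rnorm(gp$n)
  list(genome = gen, eqtl_panel = ep, gwas_panel = gp,
       eqtl = compute_marginal_stats(ep, ex$expression),
       gwas = compute_marginal_stats(gp, y),
       expression = ex, y = y)
}
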