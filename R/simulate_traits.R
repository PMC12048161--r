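#' Simulate a pair of genetically correlated quantitative traits
#'
#' Draws additive causal effects for two traits on the same variant panel
#' and returns standardized phenotypes together with the ground truth. A
#' fraction `shared_fraction` of each trait's causal variants is shared;
#' effect pairs at shared causals are bivariate normal with per-pair
#' correlation `rho_g / shared_fraction`, so the genetic correlation of the
#' two genetic values targets `rho_g`. Genetic values are rescaled to have
#' sample variance exactly `h2`, and independent Gaussian noise brings each
#' phenotype to variance 1 (optionally with environmental correlation
#' `rho_e` when the two traits are measured on the same cohort).
#'
#' @param panel an `ld_panel` with dosages `G`.
#' @param h2_1,h2_2 trait heritabilities in [0, 1].
#' @param rho_g target genetic correlation; requires
#'   `|rho_g| <= shared_fraction` (only shared causals contribute
#'   covariance).
#' @param n_causal number of causal variants per trait.
#' @param shared_fraction fraction of causal variants shared between the
#'   traits, in [0, 1].
#' @param rho_e environmental (noise) correlation, default 0; relevant when
#'   both traits are measured on the same individuals (sample overlap, which
#'   the LDSC intercept absorbs).
#' @param seed integer seed.
#' @return list with `y1`, `y2` (standardized phenotypes), `g1`, `g2`
#'   (genetic values) and `truth` (a `truth_record`): causal ids and betas
#'   per trait, shared flags, target and realized h2 / genetic correlation
#'   and covariance.
#' @export
simulate_trait_pair <- function(panel, h2_1, h2_2, rho_g, n_causal,
                                shared_fraction = 1, rho_e = 0, seed = 1L) {
  stopifnot(inherits(panel, "ld_panel"), !is.null(panel$G))
  m <- ncol(panel$G)
  n <- nrow(panel$G)
  if (h2_1 < 0 || h2_1 > 1 || h2_2 < 0 || h2_2 > 1) stop("h2 must lie in [0, 1]")
  if (n_causal < 1 || n_causal > m) stop("n_causal must be in [1, m]")
  if (shared_fraction < 0 || shared_fraction > 1) stop("shared_fraction in [0,1]")
  if (abs(rho_g) > 1) stop("|rho_g| must be <= 1")
  if (h2_1 > 0 && h2_2 > 0 && shared_fraction > 0) {
    if (abs(rho_g) > shared_fraction + 1e-12)
      stop("infeasible rho_g: |rho_g| cannot exceed shared_fraction")
  } else if (rho_g != 0) {
    stop("infeasible rho_g: needs positive h2 in both traits and shared causals")
  }
  set.seed(as.integer(seed))

  n_shared <- round(shared_fraction * n_causal)
  shared_idx <- sort(sample.int(m, n_shared))
  pool <- setdiff(seq_len(m), shared_idx)
  own1 <- sort(sample(pool, n_causal - n_shared))
  own2 <- sort(sample(setdiff(pool, own1), n_causal - n_shared))

  beta1 <- numeric(m); beta2 <- numeric(m)
  if (n_shared > 0) {
    r_pair <- if (shared_fraction > 0) rho_g / shared_fraction else 0
    u <- stats::rnorm(n_shared)
    v <- stats::rnorm(n_shared)
    b1 <- u
    b2 <- r_pair * u + sqrt(max(0, 1 - r_pair^2)) * v
    beta1[shared_idx] <- b1
    beta2[shared_idx] <- b2
  }
  beta1[own1] <- stats::rnorm(length(own1))
  beta2[own2] <- stats::rnorm(length(own2))

  if (is.null(panel$col_sd)) panel <- cache_col_stats(panel)
  idx1 <- sort(c(shared_idx, own1)); idx2 <- sort(c(shared_idx, own2))
  # genetic value over standardized dosages, via the cached column moments
  gval <- function(idx, b) {
    bs <- b[idx] / panel$col_sd[idx]
    as.numeric(panel$G[, idx, drop = FALSE] %*% bs) -
      sum(panel$col_mean[idx] * bs)
  }
  g1 <- gval(idx1, beta1)
  g2 <- gval(idx2, beta2)
  scale_to_var <- function(g, h2) {
    if (h2 == 0) return(list(g = numeric(length(g)), f = 0))
    v <- stats::var(g)
    f <- sqrt(h2 / v)
    list(g = g * f, f = f)
  }
  s1 <- scale_to_var(g1, h2_1); g1 <- s1$g; beta1 <- beta1 * s1$f
  s2 <- scale_to_var(g2, h2_2); g2 <- s2$g; beta2 <- beta2 * s2$f
  if (h2_1 == 0) beta1[] <- 0
  if (h2_2 == 0) beta2[] <- 0

  e1 <- stats::rnorm(n)
  e2 <- rho_e * e1 + sqrt(max(0, 1 - rho_e^2)) * stats::rnorm(n)
  y1 <- g1 + sqrt(max(0, 1 - h2_1)) * e1
  y2 <- g2 + sqrt(max(0, 1 - h2_2)) * e2
  y1 <- as.numeric(scale(y1))
  y2 <- as.numeric(scale(y2))

  realized_cov <- if (h2_1 > 0 && h2_2 > 0) stats::cov(g1, g2) else 0
  realized_cor <- if (h2_1 > 0 && h2_2 > 0) stats::cor(g1, g2) else 0
  truth <- structure(list(
    causal_ids = list(trait1 = panel$variant_ids[idx1],
                      trait2 = panel$variant_ids[idx2]),
    beta = list(trait1 = beta1[idx1], trait2 = beta2[idx2]),
    shared_ids = panel$variant_ids[shared_idx],
    h2 = c(h2_1, h2_2),
    rho_g_target = rho_g,
    rho_g_realized = realized_cor,
    gcov_realized = realized_cov
  ), class = "truth_record")
  list(y1 = y1, y2 = y2, g1 = g1, g2 = g2, truth = truth)
}

#' Simulate cis-regulated gene expression
#'
#' Expression is a genetic value over specified causal cis variants plus
#' Gaussian noise, standardized to variance 1. Forcing `causal_ids` to a
#' variant shared with a trait gives colocalization ground truth; forcing a
#' distinct variant in LD with a trait causal gives linkage ground truth.
#'
#' @param panel an `ld_panel` with dosages.
#' @param gene_tss 1-based TSS position of the gene.
#' @param cis_window half-width of the cis window in bases (default 2 Mb per
#'   side, the usual cis-eQTL scan range).
#' @param h2_cis cis heritability of expression in [0, 1].
#' @param causal_ids variant ids (or indices) of the causal cis variants;
#'   may be empty for a null gene.
#' @param beta optional causal effects (default i.i.d. normal).
#' @param seed integer seed.
#' @return list with `expression` (length-n standardized vector) and
#'   `truth` (a `truth_record`).
#' @export
simulate_cis_expression <- function(panel, gene_tss, cis_window = 2e6,
                                    h2_cis, causal_ids = character(),
                                    beta = NULL, seed = 1L) {
  stopifnot(inherits(panel, "ld_panel"), !is.null(panel$G))
  if (h2_cis < 0 || h2_cis > 1) stop("h2_cis must lie in [0, 1]")
  n <- nrow(panel$G)
  idx <- if (is.character(causal_ids)) match(causal_ids, panel$variant_ids)
         else as.integer(causal_ids)
  if (anyNA(idx)) stop("unknown causal id(s)")
  if (length(idx) > 0) {
    inwin <- abs(panel$pos[idx] - gene_tss) <= cis_window
    if (!all(inwin))
      stop("causal id(s) outside the cis window: ",
           paste(panel$variant_ids[idx[!inwin]], collapse = ", "))
  }
  set.seed(as.integer(seed))
  if (length(idx) == 0 || h2_cis == 0) {
    expr <- stats::rnorm(n)
    g <- numeric(n)
    b <- numeric(0)
  } else {
    b <- if (is.null(beta)) stats::rnorm(length(idx)) else beta
    Gs <- standardize_dosages(panel$G[, idx, drop = FALSE])
    g <- as.numeric(Gs %*% b)
    f <- sqrt(h2_cis / stats::var(g))
    g <- g * f; b <- b * f
    expr <- g + sqrt(max(0, 1 - h2_cis)) * stats::rnorm(n)
  }
  if (h2_cis < 1 || length(idx) == 0) expr <- as.numeric(scale(expr))
  truth <- structure(list(
    causal_ids = list(expression = panel$variant_ids[idx]),
    beta = list(expression = b),
    h2 = h2_cis,
    gene_tss = gene_tss,
    cis_window = cis_window
  ), class = "truth_record")
  list(expression = expr, genetic_value = g, truth = truth)
}

#' Per-variant marginal association scan (GWAS / cis-eQTL emitter)
#'
#' Univariate least squares of a phenotype on each standardized dosage
#' column (with intercept), the marginal model behind GWAS summary
#' statistics and Matrix-eQTL-style cis scans. On standardized y and x the
#' slope is the sample correlation, `se = sqrt((1 - r^2) / (n - 2))` and
#' `z = beta / se`.
#'
#' @param panel an `ld_panel` with dosages.
#' @param y phenotype vector, length `nrow(panel$G)`.
#' @param n_label sample size to report (default `length(y)`).
#' @param info imputation INFO value to report per variant (default 1).
#' @param maf_min,info_min optional filters applied to the emitted table
#'   (defaults keep everything; the conventional summary-stat filters are
#'   maf >= 0.01, info >= 0.95).
#' @return a `summary_stats` data frame with columns `id, chrom, pos, a1,
#'   a2, beta, se, z, n, maf, info`.
#' @export
compute_marginal_stats <- function(panel, y, n_label = NULL, info = 1,
                                   maf_min = 0, info_min = 0) {
  stopifnot(inherits(panel, "ld_panel"), !is.null(panel$G))
  n <- nrow(panel$G)
  if (length(y) != n) stop("y must have length nrow(panel$G)")
  ys <- as.numeric(scale(y))
  if (is.null(panel$col_sd)) panel <- cache_col_stats(panel)
  sds <- panel$col_sd
  keep <- sds > 0
  if (any(!keep))
    message(sum(!keep), " zero-variance dosage column(s) dropped")
  Gk <- if (all(keep)) panel$G else panel$G[, keep, drop = FALSE]
  # ys is centered, so the column means drop out of the cross-product
  r <- as.numeric(crossprod(Gk, ys)) / ((n - 1) * sds[keep])
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  beta <- r
  se <- sqrt((1 - r^2) / (n - 2))
  z <- beta / se
  ss <- data.frame(
    id = panel$variant_ids[keep],
    chrom = panel$chrom[keep],
    pos = panel$pos[keep],
    a1 = panel$a1[keep],
    a2 = panel$a2[keep],
    beta = beta, se = se, z = z,
    n = if (is.null(n_label)) n else n_label,
    maf = panel$maf[keep],
    info = info,
    stringsAsFactors = FALSE
  )
  ss <- ss[ss$maf >= maf_min & ss$info >= info_min, , drop = FALSE]
  rownames(ss) <- NULL
  class(ss) <- c("summary_stats", "data.frame")
  ss
}

validate_summary_stats <- function(ss, tol = 1e-6) {
  stopifnot(all(c("id", "chrom", "pos", "a1", "a2", "beta", "se", "z",
                  "n", "maf", "info") %in% names(ss)))
  stopifnot(all(ss$se > 0), all(abs(ss$z - ss$beta / ss$se) < tol),
            all(ss$maf > 0), all(ss$maf <= 0.5),
            all(ss$info >= 0), all(ss$info <= 1))
  invisible(TRUE)
}
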