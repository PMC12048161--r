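#' Compute LD scores from a reference panel
#'
#' The LD score of variant j is the sum of squared correlations with all
#' variants within `window` bases on the same chromosome (including
#' itself), optionally with the small-sample bias adjustment
#' `r2_adj = r2 - (1 - r2) / (n_ref - 2)`. Per-annotation scores restrict
#' the sum to annotation members, so for a full partition the annotation
#' scores sum to the global score.
#'
#' @param panel an `ld_panel` (uses `R` if stored, otherwise computes
#'   windowed correlations from `G`).
#' @param window window half-width in bases (default 2 Mb).
#' @param annotations optional m x C logical/0-1 matrix of annotation
#'   membership (columns named).
#' @param adjust apply the n_ref bias adjustment (default TRUE; requires
#'   `n_ref >= 3`).
#' @param n_ref reference sample size for the adjustment (default
#'   `panel$n`).
#' @return object of class `ld_scores`: `l` (global score per variant),
#'   `l_annot` (m x C matrix or NULL), `M`, `M_annot`, `annotations`, and
#'   the variant map (`ids`, `chrom`, `pos`).
#' @export
compute_ld_scores <- function(panel, window = 2e6, annotations = NULL,
                              adjust = TRUE, n_ref = NULL) {
  stopifnot(inherits(panel, "ld_panel"))
  if (window <= 0) stop("window must be positive")
  m <- length(panel$variant_ids)
  if (is.null(n_ref)) n_ref <- panel$n
  if (adjust && (is.null(n_ref) || n_ref < 3))
    stop("bias adjustment requires n_ref >= 3")
  if (!is.null(annotations)) {
    annotations <- as.matrix(annotations) != 0
    stopifnot(nrow(annotations) == m)
    if (is.null(colnames(annotations)))
      colnames(annotations) <- paste0("annot", seq_len(ncol(annotations)))
  }
  R <- panel$R
  have_R <- !is.null(R)
  if (!have_R && is.null(panel$G)) stop("panel must carry R or G")

  l <- numeric(m)
  l_annot <- if (is.null(annotations)) NULL else
    matrix(0, m, ncol(annotations), dimnames = list(NULL, colnames(annotations)))
  # process in chunks of contiguous variants sharing a window superset
  chunk <- 256L
  starts <- seq(1L, m, by = chunk)
  for (s in starts) {
    js <- s:min(s + chunk - 1L, m)
    lo <- panel$pos[js[1]] - window
    hi <- panel$pos[js[length(js)]] + window
    ks <- which(panel$chrom == panel$chrom[js[1]] &
                panel$pos >= lo & panel$pos <= hi)
    r <- if (have_R) R[js, ks, drop = FALSE]
         else fast_cor(panel$G[, js, drop = FALSE],
                       panel$G[, ks, drop = FALSE])
    r2 <- r^2
    if (adjust) r2 <- r2 - (1 - r2) / (n_ref - 2)
    inwin <- outer(panel$pos[js], panel$pos[ks],
                   function(a, b) abs(a - b) <= window) &
             outer(panel$chrom[js], panel$chrom[ks], "==")
    r2[!inwin] <- 0
    l[js] <- rowSums(r2)
    if (!is.null(annotations))
      for (cidx in seq_len(ncol(annotations)))
        l_annot[js, cidx] <- rowSums(r2[, annotations[ks, cidx], drop = FALSE])
  }
  structure(list(l = l, l_annot = l_annot, M = m,
                 M_annot = if (is.null(annotations)) NULL else colSums(annotations),
                 annotations = annotations,
                 ids = panel$variant_ids, chrom = panel$chrom,
                 pos = panel$pos, n_ref = n_ref, adjust = adjust,
                 window = window),
            class = "ld_scores")
}

#' @export
print.ld_scores <- function(x, ...) {
  cat("LD scores for", x$M, "variants (window", x$window, "bp);",
      if (is.null(x$l_annot)) "no annotations"
      else paste(ncol(x$l_annot), "annotation(s)"), "\n")
  invisible(x)
}

#' Gene-window annotation for partitioned covariance
#'
#' Marks variants inside windows of `half_width` bases around each TSS
#' (so the default spans 4 Mb per gene) and adds the complement, giving a
#' full two-annotation partition.
#'
#' @param scores_or_panel an `ld_scores` or `ld_panel` (for the variant map).
#' @param tss vector of TSS positions (same chromosome naming as the map).
#' @param chrom chromosome per TSS (default: recycle the map's single
#'   chromosome).
#' @param half_width half-width in bases (default 2 Mb, i.e. a 4 Mb window).
#' @return m x 2 logical matrix with columns `target`, `complement`.
#' @export
gene_window_annotation <- function(scores_or_panel, tss, chrom = NULL,
                                   half_width = 2e6) {
  map_chrom <- if (inherits(scores_or_panel, "ld_scores")) scores_or_panel$chrom
               else scores_or_panel$chrom
  map_pos <- scores_or_panel$pos
  if (is.null(chrom)) chrom <- rep(map_chrom[1], length(tss))
  inside <- rep(FALSE, length(map_pos))
  for (i in seq_along(tss))
    inside <- inside | (map_chrom == chrom[i] &
                        abs(map_pos - tss[i]) <= half_width)
  cbind(target = inside, complement = !inside)
}

# --- allele alignment -------------------------------------------------------

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align two summary-statistic tables on shared variants
#'
#' Intersects on id, harmonizes alleles (an a1/a2 swap flips the sign of z
#' and beta; strand flips are resolved via the complement), drops
#' strand-ambiguous (A/T, C/G) and irreconcilable variants, and reports
#' counts.
#'
#' @param ss1,ss2 `summary_stats` data frames.
#' @param drop_ambiguous drop A/T and C/G variants (default TRUE).
#' @return list `ss1`, `ss2` (row-matched, ss2 re-oriented to ss1's
#'   alleles), `n_flipped`, `n_dropped`.
#' @export
align_summary_stats <- function(ss1, ss2, drop_ambiguous = TRUE) {
  common <- intersect(ss1$id, ss2$id)
  s1 <- ss1[match(common, ss1$id), , drop = FALSE]
  s2 <- ss2[match(common, ss2$id), , drop = FALSE]
  a1_1 <- toupper(s1$a1); a2_1 <- toupper(s1$a2)
  a1_2 <- toupper(s2$a1); a2_2 <- toupper(s2$a2)
  same <- a1_1 == a1_2 & a2_1 == a2_2
  swap <- a1_1 == a2_2 & a2_1 == a1_2
  fl_same <- COMPLEMENT[a1_1] == a1_2 & COMPLEMENT[a2_1] == a2_2
  fl_swap <- COMPLEMENT[a1_1] == a2_2 & COMPLEMENT[a2_1] == a1_2
  flip <- (swap | (fl_swap & !fl_same)) & !same
  ok <- same | swap | fl_same | fl_swap
  if (drop_ambiguous) ok <- ok & !is_strand_ambiguous(a1_1, a2_1)
  s2$z[flip] <- -s2$z[flip]
  s2$beta[flip] <- -s2$beta[flip]
  s2$a1 <- s1$a1; s2$a2 <- s1$a2
  list(ss1 = s1[ok, , drop = FALSE], ss2 = s2[ok, , drop = FALSE],
       n_flipped = sum(flip & ok),
       n_dropped = length(common) - sum(ok))
}

# delete-one-block weighted least squares machinery: X is (1, x) or wider
.block_wls <- function(X, y, w, blocks) {
  p <- ncol(X)
  Xw <- X * w
  XtX_tot <- crossprod(Xw, X)
  Xty_tot <- crossprod(Xw, y)
  nb <- max(blocks)
  XtX_b <- array(0, c(p, p, nb))
  Xty_b <- matrix(0, p, nb)
  for (b in seq_len(nb)) {
    i <- which(blocks == b)
    Xw_i <- X[i, , drop = FALSE] * w[i]
    XtX_b[, , b] <- crossprod(Xw_i, X[i, , drop = FALSE])
    Xty_b[, b] <- crossprod(Xw_i, y[i])
  }
  full <- solve(XtX_tot, Xty_tot)
  del <- matrix(0, p, nb)
  for (b in seq_len(nb))
    del[, b] <- solve(XtX_tot - XtX_b[, , b], Xty_tot - Xty_b[, b])
  list(coef = drop(full), delete = del, n_blocks = nb)
}

.jackknife_se <- function(theta_del) {
  nb <- length(theta_del)
  thbar <- mean(theta_del)
  sqrt((nb - 1) / nb * sum((theta_del - thbar)^2))
}

#' Cross-trait LD score regression
#'
#' Estimates heritabilities, genetic covariance and genetic correlation of
#' two traits from summary statistics and LD scores. The cross-trait
#' regression fits `E[z1 z2] = sqrt(N1 N2) rho_g l_j / M + intercept` by
#' two-step weighted least squares (heteroskedasticity weights from a
#' first pass, LD-scores also downweighting); univariate fits of `z^2`
#' supply the heritabilities. Standard errors and the p-value for rg = 0
#' come from a delete-one block jackknife over contiguous variant blocks.
#' The intercepts are free, absorbing sample overlap.
#'
#' @param ss1,ss2 `summary_stats` for the two traits.
#' @param scores an `ld_scores` on (a superset of) the shared variants.
#' @param n_blocks jackknife blocks (default 200).
#' @return object of class `rg_estimate`.
#' @export
cross_trait_ldsc <- function(ss1, ss2, scores, n_blocks = 200) {
  al <- align_summary_stats(ss1, ss2)
  s1 <- al$ss1; s2 <- al$ss2
  keep <- match(s1$id, scores$ids)
  ok <- !is.na(keep)
  s1 <- s1[ok, ]; s2 <- s2[ok, ]
  l <- scores$l[keep[ok]]
  mvar <- nrow(s1)
  if (mvar < 10 * n_blocks)
    stop("need at least 10 x n_blocks variants after alignment (have ",
         mvar, ")")
  M <- scores$M
  lf <- pmax(l, 1)
  blocks <- ceiling(seq_len(mvar) / (mvar / n_blocks))

  uni <- function(z, N) {
    # (coefficients are unnamed scalars throughout)
    x <- N * l / M
    X <- cbind(1, x)
    w0 <- 1 / lf
    fit0 <- stats::lm.wfit(X, z^2, w0)
    h2_0 <- max(0, fit0$coefficients[2])
    w <- 1 / (lf * (1 + mean(N) * h2_0 * l / M)^2)
    bw <- .block_wls(X, z^2, w, blocks)
    list(h2 = unname(bw$coef[2]), int = unname(bw$coef[1]),
         del = bw$delete[2, ], w = w, h2_0 = h2_0)
  }
  u1 <- uni(s1$z, s1$n)
  u2 <- uni(s2$z, s2$n)

  x12 <- sqrt(s1$n * s2$n) * l / M
  X12 <- cbind(1, x12)
  w0 <- 1 / lf
  fit0 <- stats::lm.wfit(X12, s1$z * s2$z, w0)
  rho0 <- unname(fit0$coefficients[2]); int0 <- unname(fit0$coefficients[1])
  het <- (1 + mean(s1$n) * max(0, u1$h2_0) * l / M) *
         (1 + mean(s2$n) * max(0, u2$h2_0) * l / M) +
         (int0 + rho0 * x12)^2
  w12 <- 1 / (lf * pmax(het, 1e-8))
  bw <- .block_wls(X12, s1$z * s2$z, w12, blocks)
  rho_g <- unname(bw$coef[2]); intercept_x <- unname(bw$coef[1])

  h2_1 <- u1$h2; h2_2 <- u2$h2
  rg_defined <- h2_1 > 0 && h2_2 > 0
  rg <- if (rg_defined) rho_g / sqrt(h2_1 * h2_2) else NA_real_

  rg_del <- rep(NA_real_, n_blocks)
  if (rg_defined) {
    okb <- u1$del > 0 & u2$del > 0
    rg_del[okb] <- bw$delete[2, okb] / sqrt(u1$del[okb] * u2$del[okb])
    rg_del[!okb] <- rg # degenerate block: fall back to full estimate
  }
  se <- list(
    rho_g = .jackknife_se(bw$delete[2, ]),
    h2_1 = .jackknife_se(u1$del),
    h2_2 = .jackknife_se(u2$del),
    rg = if (rg_defined) .jackknife_se(rg_del) else NA_real_
  )
  p_value <- if (rg_defined && se$rg > 0)
    2 * stats::pnorm(-abs(rg) / se$rg) else NA_real_
  structure(list(
    rho_g = rho_g, h2_1 = h2_1, h2_2 = h2_2, rg = rg,
    intercepts = c(trait1 = u1$int, trait2 = u2$int, cross = intercept_x),
    se = se, p_value = p_value,
    n_blocks = n_blocks, n_variants = mvar,
    n_dropped = al$n_dropped, n_flipped = al$n_flipped,
    rg_defined = rg_defined,
    rg_out_of_bounds = rg_defined && abs(rg) > 1
  ), class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat("Cross-trait LDSC on", x$n_variants, "variants (",
      x$n_blocks, "jackknife blocks )\n")
  cat(sprintf("  h2_1 = %.4f (%.4f)  h2_2 = %.4f (%.4f)\n",
              x$h2_1, x$se$h2_1, x$h2_2, x$se$h2_2))
  cat(sprintf("  rho_g = %.4f (%.4f)\n", x$rho_g, x$se$rho_g))
  if (x$rg_defined)
    cat(sprintf("  rg = %.4f (%.4f), p = %.3g%s\n", x$rg, x$se$rg,
                x$p_value,
                if (x$rg_out_of_bounds) "  [out of bounds]" else ""))
  else cat("  rg undefined (non-positive h2 estimate)\n")
  invisible(x)
}

#' Partitioned (annotation-stratified) genetic covariance
#'
#' Stratified cross-trait regression of `z1 z2` on per-annotation LD
#' scores: `E[z1 z2] = sqrt(N1 N2) sum_c (rho_c / M_c) l_jc + intercept`,
#' for a full partition (annotation set plus complement). Per-annotation
#' covariance, its jackknife SE, and the covariance fraction vs the SNP
#' fraction are reported.
#'
#' @param ss1,ss2 `summary_stats`.
#' @param scores `ld_scores` with annotations forming a full partition.
#' @param n_blocks jackknife blocks (default 200).
#' @param min_variants annotations with fewer members are flagged unstable.
#' @return object of class `partitioned_cov`: per-annotation data frame
#'   plus totals.
#' @export
partitioned_covariance <- function(ss1, ss2, scores, n_blocks = 200,
                                   min_variants = 50) {
  if (is.null(scores$l_annot)) stop("scores must carry annotations")
  if (max(abs(rowSums(scores$l_annot) - scores$l)) > 1e-6)
    stop("annotations must form a full partition (sum of l_jc must equal l_j)")
  al <- align_summary_stats(ss1, ss2)
  s1 <- al$ss1; s2 <- al$ss2
  keep <- match(s1$id, scores$ids)
  ok <- !is.na(keep)
  s1 <- s1[ok, ]; s2 <- s2[ok, ]
  idx <- keep[ok]
  l <- scores$l[idx]
  LA <- scores$l_annot[idx, , drop = FALSE]
  Mc <- scores$M_annot
  M <- scores$M
  mvar <- nrow(s1)
  blocks <- ceiling(seq_len(mvar) / (mvar / n_blocks))
  unstable <- Mc < min_variants
  if (any(unstable))
    warning("annotation(s) with < ", min_variants, " variants: ",
            paste(names(Mc)[unstable], collapse = ", "))

  use <- Mc > 0
  if (!all(use))
    warning("annotation(s) with no member variants dropped from the fit: ",
            paste(names(Mc)[!use], collapse = ", "))
  sn <- sqrt(s1$n * s2$n)
  X <- cbind(1, sweep(LA[, use, drop = FALSE], 2L, Mc[use], "/") * sn)
  y <- s1$z * s2$z
  lf <- pmax(l, 1)
  fit0 <- stats::lm.wfit(X, y, 1 / lf)
  rho0 <- sum(fit0$coefficients[-1])
  het <- 1 + (fit0$coefficients[1] + sn * rho0 * l / M)^2
  w <- 1 / (lf * pmax(het, 1e-8))
  bw <- .block_wls(X, y, w, blocks)
  rho_c <- rep(0, length(Mc)); rho_c[use] <- unname(bw$coef[-1])
  del_c <- matrix(0, length(Mc), ncol(bw$delete))
  del_c[use, ] <- bw$delete[-1, , drop = FALSE]
  rho_tot <- sum(rho_c)
  del_tot <- colSums(del_c)
  cov_fraction <- rho_c / rho_tot
  cf_del <- sweep(del_c, 2L, del_tot, "/")
  res <- data.frame(
    annotation = names(Mc),
    M_annot = as.integer(Mc),
    snp_fraction = Mc / M,
    rho_c = rho_c,
    se = apply(del_c, 1L, .jackknife_se),
    cov_fraction = cov_fraction,
    cov_fraction_se = apply(cf_del, 1L, .jackknife_se),
    unstable = unstable,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  structure(list(table = res, rho_total = rho_tot,
                 rho_total_se = .jackknife_se(del_tot),
                 intercept = bw$coef[1], n_variants = mvar,
                 n_blocks = n_blocks),
            class = "partitioned_cov")
}

#' @export
print.partitioned_cov <- function(x, ...) {
  cat("Partitioned genetic covariance (", x$n_variants, "variants )\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Monte Carlo enrichment test for a covariance fraction
#'
#' Draws `(rho_c, rho_tot)` from independent normals centered at the point
#' estimates with the given SEs, forms the covariance fraction
#' `rho_c / rho_tot` per draw, and reports the one-sided p-value (the
#' proportion of draws with fraction <= the SNP fraction) and the log2
#' enrichment of the median fraction over the SNP fraction. Draws in which
#' the total covariance crosses zero (changes sign relative to the point
#' estimate) are excluded and counted; if more than half are excluded the
#' result is flagged unreliable.
#'
#' @param rho_c,se_c annotation covariance estimate and SE.
#' @param rho_total,se_total total covariance estimate and SE.
#' @param snp_fraction fraction of variants in the annotation, in (0, 1).
#' @param n_draws Monte Carlo draws (default 50000).
#' @param seed integer seed.
#' @param label annotation label carried through.
#' @return object of class `enrichment_result`.
#' @export
mc_enrichment <- function(rho_c, se_c, rho_total, se_total, snp_fraction,
                          n_draws = 50000, seed = 1L, label = "annotation") {
  if (se_c < 0 || se_total < 0) stop("SEs must be non-negative")
  if (snp_fraction <= 0 || snp_fraction >= 1)
    stop("snp_fraction must lie in (0, 1)")
  if (rho_total == 0) stop("total covariance of zero: fraction undefined")
  set.seed(as.integer(seed))
  rc <- rho_c + se_c * stats::rnorm(n_draws)
  rt <- rho_total + se_total * stats::rnorm(n_draws)
  keep <- sign(rt) == sign(rho_total) & rt != 0
  n_excluded <- sum(!keep)
  frac <- rc[keep] / rt[keep]
  p <- mean(frac <= snp_fraction)
  med <- stats::median(frac)
  structure(list(
    annotation = label,
    cov_fraction = stats::median(frac),
    snp_fraction = snp_fraction,
    log2_enrichment = log2(med / snp_fraction),
    one_sided_p = p,
    n_draws = n_draws,
    n_excluded = n_excluded,
    unreliable = n_excluded > n_draws / 2
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "MC enrichment [%s]: cov fraction %.4f vs SNP fraction %.4f, log2 = %.3f, one-sided p = %.4g%s\n",
    x$annotation, x$cov_fraction, x$snp_fraction, x$log2_enrichment,
    x$one_sided_p, if (x$unreliable) " [unreliable]" else ""))
  invisible(x)
}
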