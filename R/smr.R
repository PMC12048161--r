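#' Select the instrument variant (top cis-eQTL)
#'
#' Returns the id of the variant with the largest |z| in the cis scan,
#' provided its p-value passes `p_threshold`; ties in |z| are broken by
#' smallest position. Returns `NA` when no variant qualifies.
#'
#' @param eqtl `summary_stats` restricted to one gene's cis window.
#' @param p_threshold instrument significance threshold (default 5e-8).
#' @return variant id or `NA_character_`.
#' @export
select_instrument <- function(eqtl, p_threshold = 5e-8) {
  if (nrow(eqtl) == 0) {
    message("empty cis scan: no instrument")
    return(NA_character_)
  }
  ord <- order(-abs(eqtl$z), eqtl$pos)
  top <- eqtl[ord[1], ]
  p_top <- 2 * stats::pnorm(-abs(top$z))
  if (p_top < p_threshold) top$id else NA_character_
}

#' SMR test statistic for a gene-trait pair
#'
#' With the top cis-eQTL as instrument, the Wald ratio
#' `b_smr = b_gwas / b_eqtl` estimates the effect of expression on the
#' trait. The test statistic is
#' `T_smr = z_gwas^2 z_eqtl^2 / (z_gwas^2 + z_eqtl^2)`, approximately
#' chi-square with 1 df under the null, and
#' `se_smr = |b_smr| / sqrt(T_smr)`.
#'
#' @param z_eqtl,z_gwas instrument z-scores in the eQTL and GWAS scans.
#' @param b_eqtl,b_gwas instrument effect sizes.
#' @return list `b_smr`, `se_smr`, `T_smr`, `p_smr`.
#' @export
smr_test <- function(z_eqtl, z_gwas, b_eqtl, b_gwas) {
  if (z_eqtl == 0) stop("z_eqtl = 0: no instrument")
  T_smr <- (z_gwas^2 * z_eqtl^2) / (z_gwas^2 + z_eqtl^2)
  b_smr <- b_gwas / b_eqtl
  se_smr <- if (T_smr > 0) abs(b_smr) / sqrt(T_smr) else Inf
  list(b_smr = b_smr, se_smr = se_smr, T_smr = T_smr,
       p_smr = stats::pchisq(T_smr, df = 1, lower.tail = FALSE))
}

#' Approximate posterior probability of association from the SMR statistic
#'
#' Wakefield-style approximate Bayes factor on the 1-df statistic with
#' prior effect variance `W`: `ABF = sqrt(V/(V+W)) exp(W T / (2 (V+W)))`
#' with `V = se_smr^2`, combined with prior probability `prior_pi` of a
#' real effect: `PPA = ABF pi / (ABF pi + 1 - pi)`. Monotone increasing in
#' `T_smr` at fixed `V`, so thresholding PPA at 0.5 thresholds the SMR
#' evidence.
#'
#' @param T_smr SMR chi-square statistic.
#' @param se_smr SMR standard error (supplies `V = se_smr^2`).
#' @param prior_pi prior probability of association, in (0, 1);
#'   default 0.01.
#' @param W prior effect-size variance; default 0.15^2.
#' @return posterior probability in [0, 1].
#' @export
ppa_from_smr <- function(T_smr, se_smr, prior_pi = 0.01, W = 0.15^2) {
  if (prior_pi <= 0 || prior_pi >= 1) stop("prior_pi must lie in (0, 1)")
  if (W <= 0) stop("W must be positive")
  V <- se_smr^2
  labf <- 0.5 * log(V / (V + W)) + W * T_smr / (2 * (V + W))
  # odds form, stable for large ABF
  lodds <- labf + log(prior_pi) - log1p(-prior_pi)
  1 / (1 + exp(-lodds))
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Tests whether the Wald ratios `b_gwas(i) / b_eqtl(i)` at cis variants in
#' LD with the instrument are consistent with a single shared causal
#' variant. Eligible variants have eQTL chi-square > `chi2_min` and
#' r-squared to the instrument within `[r2_min, r2_max]` (at most
#' `max_snps`, strongest eQTL first). The differences
#' `d_i = b_smr(i) - b_smr(instrument)` are combined via the delta method
#' with the LD-induced covariance; the sum of squared standardized
#' differences is referred to a Satterthwaite-matched scaled chi-square.
#'
#' @param eqtl,gwas `summary_stats` on the locus (will be aligned).
#' @param panel `ld_panel` supplying LD for the eQTL-side effect
#'   covariance and the eligibility r-squared (the eQTL / reference
#'   cohort).
#' @param instrument instrument variant id.
#' @param r2_min,r2_max LD eligibility bounds (defaults 0.05, 0.9).
#' @param max_snps maximum test variants (default 20).
#' @param chi2_min eQTL chi-square eligibility (default 10).
#' @param panel_gwas optional `ld_panel` for the GWAS-side effect
#'   covariance (defaults to `panel`); each cohort's effect estimates are
#'   correlated through its own sample LD.
#' @return list `p_heidi` (NA when untested), `n_snps`, `untested`.
#' @export
heidi_test <- function(eqtl, gwas, panel, instrument,
                       r2_min = 0.05, r2_max = 0.9, max_snps = 20,
                       chi2_min = 10, panel_gwas = NULL) {
  al <- align_summary_stats(eqtl, gwas)
  e <- al$ss1; g <- al$ss2
  keep <- match(e$id, panel$variant_ids)
  ok <- !is.na(keep)
  e <- e[ok, ]; g <- g[ok, ]
  pidx <- keep[ok]
  i0 <- which(e$id == instrument)
  if (length(i0) != 1)
    stop("instrument must be present in both scans and the panel")
  panel_R <- function(pn, ids) {
    j <- match(ids, pn$variant_ids)
    if (anyNA(j)) stop("variant(s) missing from the LD panel")
    if (!is.null(pn$R)) pn$R[j, j, drop = FALSE]
    else fast_cor(pn$G[, j, drop = FALSE])
  }
  R <- panel_R(panel, e$id)
  Rg <- if (is.null(panel_gwas)) R else panel_R(panel_gwas, e$id)
  r_to_top <- R[, i0]
  elig <- which(e$z^2 > chi2_min &
                r_to_top^2 >= r2_min & r_to_top^2 <= r2_max)
  elig <- setdiff(elig, i0)
  if (length(elig) > max_snps)
    elig <- elig[order(-e$z[elig]^2)][seq_len(max_snps)]
  if (length(elig) < 3)
    return(list(p_heidi = NA_real_, n_snps = length(elig), untested = TRUE))

  sel <- c(i0, elig)
  bzx <- e$beta[sel]; se_zx <- e$se[sel]
  bzy <- g$beta[sel]; se_zy <- g$se[sel]
  Rs <- R[sel, sel, drop = FALSE]
  Rgs <- Rg[sel, sel, drop = FALSE]
  b_xy <- bzy / bzx
  # delta-method covariance of the Wald ratios (eQTL and GWAS cohorts
  # independent; each cohort's effect estimates correlated through its
  # own sample LD)
  k <- length(sel)
  cov_bxy <- Rgs * tcrossprod(se_zy) / tcrossprod(bzx) +
             Rs * tcrossprod(bzy) * tcrossprod(se_zx) / tcrossprod(bzx^2)
  # d_i = b_xy(i) - b_xy(top), i = 2..k
  A <- cbind(-1, diag(k - 1))        # maps b_xy to d
  Vd <- A %*% cov_bxy %*% t(A)
  d <- b_xy[-1] - b_xy[1]
  sdd <- sqrt(diag(Vd))
  zd <- d / sdd
  Cz <- Vd / tcrossprod(sdd)
  T_heidi <- sum(zd^2)
  # T is a quadratic form sum lambda_i chi2_1 with lambda the eigenvalues
  # of the correlation matrix of z_d; four-moment (Liu-Tang-Zhang)
  # chi-square approximation for the upper tail
  lambda <- eigen(Cz, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  p <- quadform_pvalue(T_heidi, lambda)
  list(p_heidi = p, n_snps = length(elig), untested = FALSE)
}

# upper-tail probability of sum lambda_i chi2_1 by the Liu-Tang-Zhang
# moment-matched noncentral chi-square (matches skewness, and kurtosis when
# attainable); reduces to the exact chi-square for equal lambda
quadform_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  if (c2 <= 0) return(1)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    delta <- 0
    df <- 1 / s2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- df + delta; sigma_x <- sqrt(2 * (df + 2 * delta))
  tstar <- (q - mu_q) / sigma_q * sigma_x + mu_x
  stats::pchisq(tstar, df = df, ncp = delta, lower.tail = FALSE)
}

#' Run SMR + HEIDI for one gene against one trait
#'
#' Convenience wrapper: selects the instrument from the cis-eQTL scan,
#' computes the SMR statistic, the approximate PPA and the HEIDI p-value,
#' and applies the discovery rule `PPA >= ppa_min` and
#' `p_heidi >= heidi_alpha` (genes untested by HEIDI pass by default,
#' flagged).
#'
#' @param eqtl cis-eQTL `summary_stats` for the gene.
#' @param gwas GWAS `summary_stats` for the trait.
#' @param panel LD reference `ld_panel` (eQTL side; see [heidi_test()]).
#' @param gene,tissue,trait labels carried into the result.
#' @param p_instrument instrument threshold (default 5e-8).
#' @param ppa_min PPA threshold (default 0.5).
#' @param heidi_alpha HEIDI rejection level (default 0.05).
#' @param prior_pi,W passed to [ppa_from_smr()].
#' @param ... passed to [heidi_test()].
#' @return one-row data frame of class `smr_result` (NULL if no
#'   instrument).
#' @export
run_smr <- function(eqtl, gwas, panel, gene = "gene", tissue = "tissue",
                    trait = "trait", p_instrument = 5e-8, ppa_min = 0.5,
                    heidi_alpha = 0.05, prior_pi = 0.01, W = 0.15^2, ...) {
  inst <- select_instrument(eqtl, p_instrument)
  if (is.na(inst)) return(NULL)
  ei <- eqtl[eqtl$id == inst, ]
  gi <- gwas[gwas$id == inst, ]
  if (nrow(gi) != 1) return(NULL)
  # orient the GWAS record to the eQTL alleles
  if (toupper(gi$a1) == toupper(ei$a2) && toupper(gi$a2) == toupper(ei$a1)) {
    gi$z <- -gi$z; gi$beta <- -gi$beta
  }
  sm <- smr_test(ei$z, gi$z, ei$beta, gi$beta)
  ppa <- ppa_from_smr(sm$T_smr, sm$se_smr, prior_pi = prior_pi, W = W)
  hd <- heidi_test(eqtl, gwas, panel, inst, ...)
  pass_heidi <- hd$untested || hd$p_heidi >= heidi_alpha
  out <- data.frame(
    gene = gene, tissue = tissue, trait = trait, instrument = inst,
    b_smr = sm$b_smr, se_smr = sm$se_smr, T_smr = sm$T_smr,
    p_smr = sm$p_smr, ppa = ppa, p_heidi = hd$p_heidi,
    n_heidi_snps = hd$n_snps, heidi_untested = hd$untested,
    pass = ppa >= ppa_min && pass_heidi,
    stringsAsFactors = FALSE
  )
  class(out) <- c("smr_result", "data.frame")
  out
}

#' Genes pleiotropic with the focal trait and the endophenotype panel
#'
#' From a table of SMR results across gene x tissue x trait combinations,
#' returns the genes passing the discovery rule (PPA and HEIDI) for the
#' focal trait AND for at least one endophenotype in at least one tissue.
#' Per gene, the maximum-PPA trait/tissue combination is reported for each
#' side.
#'
#' @param results data frame of `run_smr` rows (rbind-ed).
#' @param focal_trait name of the focal trait in `results$trait`.
#' @return data frame, one row per discovered gene (zero rows when none).
#' @export
discover_pleiotropic_genes <- function(results, focal_trait) {
  empty <- data.frame(gene = character(), focal_ppa = numeric(),
                      focal_tissue = character(), endo_trait = character(),
                      endo_tissue = character(), endo_ppa = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(results) || nrow(results) == 0) return(empty)
  pass <- results[results$pass, , drop = FALSE]
  if (nrow(pass) == 0) return(empty)
  out <- lapply(unique(pass$gene), function(g) {
    pg <- pass[pass$gene == g, , drop = FALSE]
    foc <- pg[pg$trait == focal_trait, , drop = FALSE]
    endo <- pg[pg$trait != focal_trait, , drop = FALSE]
    if (nrow(foc) == 0 || nrow(endo) == 0) return(NULL)
    bf <- foc[which.max(foc$ppa), ]
    be <- endo[which.max(endo$ppa), ]
    data.frame(gene = g, focal_ppa = bf$ppa, focal_tissue = bf$tissue,
               endo_trait = be$trait, endo_tissue = be$tissue,
               endo_ppa = be$ppa, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}
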