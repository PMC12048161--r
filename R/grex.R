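#' Residualize expression on covariates
#'
#' Least-squares residuals of the expression vector on a covariate matrix
#' (an intercept is always included), re-standardized to mean 0,
#' variance 1.
#'
#' @param expression numeric vector.
#' @param covariates numeric matrix (rows = individuals) or NULL for
#'   intercept-only.
#' @return standardized residual vector.
#' @export
residualize <- function(expression, covariates = NULL) {
  n <- length(expression)
  X <- cbind(intercept = rep(1, n), covariates)
  if (qr(X)$rank < ncol(X)) stop("covariates are rank-deficient")
  res <- stats::lm.fit(X, expression)$residuals
  if (stats::sd(res) < 1e-10 * max(stats::sd(expression), 1e-300))
    return(res)  # expression was (numerically) linear in the covariates
  as.numeric(scale(res))
}

#' Train a cis-window elastic-net expression model
#'
#' Fits an elastic net of (residualized) expression on standardized cis
#' dosages within `cis` bases of the TSS, on a seed-deterministic 80/20
#' train/holdout split. The model passes when the signed Pearson
#' correlation between predicted and measured expression on the holdout is
#' at least `r_min` and the predictions have nonzero variance.
#'
#' @param panel training `ld_panel`.
#' @param expression residualized expression vector (length n).
#' @param tss gene TSS position.
#' @param cis cis half-width in bases (default 1 Mb).
#' @param gene,tissue labels.
#' @param train_fraction training split (default 0.8).
#' @param alpha elastic-net mixing parameter (default 0.5); penalty
#'   strength by cross-validation on the training split.
#' @param r_min holdout signed-correlation filter (default 0.1).
#' @param nfolds cross-validation folds (default 5).
#' @param seed integer seed (controls split and CV folds).
#' @return object of class `gene_model` (NULL when no cis variants):
#'   variant ids/alleles, weights on the standardized-dosage scale with
#'   MAF recorded, holdout r, pass flag.
#' @export
train_grex <- function(panel, expression, tss, cis = 1e6,
                       gene = "gene", tissue = "tissue",
                       train_fraction = 0.8, alpha = 0.5, r_min = 0.1,
                       nfolds = 5, seed = 1L) {
  stopifnot(inherits(panel, "ld_panel"), !is.null(panel$G))
  n <- nrow(panel$G)
  if (length(expression) != n) stop("expression length must equal panel n")
  cis_idx <- which(abs(panel$pos - tss) <= cis)
  if (length(cis_idx) == 0) return(NULL)
  n_train <- round(train_fraction * n)
  if (n_train < 50) stop("need at least 50 training individuals")
  set.seed(as.integer(seed))
  train <- sort(sample.int(n, n_train))
  test <- setdiff(seq_len(n), train)

  Graw <- panel$G[, cis_idx, drop = FALSE]
  mu <- colMeans(Graw[train, , drop = FALSE])
  sdv <- apply(Graw[train, , drop = FALSE], 2L, stats::sd)
  usable <- sdv > 0
  Xtr <- scale(Graw[train, usable, drop = FALSE], center = mu[usable],
               scale = sdv[usable])
  Xte <- scale(Graw[test, usable, drop = FALSE], center = mu[usable],
               scale = sdv[usable])
  fit <- glmnet::cv.glmnet(Xtr, expression[train], alpha = alpha,
                           nfolds = nfolds, standardize = FALSE)
  w <- as.numeric(stats::coef(fit, s = "lambda.min"))
  intercept <- w[1]
  weights <- w[-1]
  pred <- as.numeric(Xte %*% weights) + intercept
  nonzero_var <- stats::sd(pred) > 0
  holdout_r <- if (nonzero_var) stats::cor(pred, expression[test]) else NA_real_
  structure(list(
    gene = gene, tissue = tissue,
    variant_ids = panel$variant_ids[cis_idx][usable],
    a1 = panel$a1[cis_idx][usable], a2 = panel$a2[cis_idx][usable],
    maf = panel$maf[cis_idx][usable],
    weights = weights, intercept = intercept,
    center = mu[usable], scale = sdv[usable],
    alpha = alpha, lambda = fit$lambda.min,
    holdout_r = holdout_r,
    pass = nonzero_var && !is.na(holdout_r) && holdout_r >= r_min,
    n_train = n_train, n_test = length(test), seed = seed
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "GReX model %s / %s: %d cis variants, %d nonzero weights, holdout r = %.3f [%s]\n",
    x$gene, x$tissue, length(x$weights), sum(x$weights != 0),
    x$holdout_r, if (x$pass) "pass" else "fail"))
  invisible(x)
}

#' Impute genetically regulated expression into a target cohort
#'
#' Linear score over the target dosages using the stored weights (on the
#' training standardization scale). Model variants absent from the target
#' are dropped with the fraction logged; a1/a2-swapped encodings are
#' aligned by flipping the dosage (2 - G).
#'
#' @param model a `gene_model`.
#' @param target target `ld_panel`.
#' @param max_missing maximum tolerated fraction of missing model variants
#'   (default 0.5; beyond it imputation is refused).
#' @return numeric GReX vector (length = target individuals), with
#'   attribute `missing_fraction`.
#' @export
impute_grex <- function(model, target, max_missing = 0.5) {
  stopifnot(inherits(model, "gene_model"), inherits(target, "ld_panel"))
  idx <- match(model$variant_ids, target$variant_ids)
  present <- !is.na(idx)
  missing_fraction <- mean(!present)
  if (missing_fraction > max_missing)
    stop(sprintf("imputation refused: %.0f%% of model variants missing",
                 100 * missing_fraction))
  if (missing_fraction > 0)
    message(sprintf("%.1f%% of model variants missing from target; dropped",
                    100 * missing_fraction))
  G <- target$G[, idx[present], drop = FALSE]
  swap <- toupper(model$a1[present]) == toupper(target$a2[idx[present]]) &
          toupper(model$a2[present]) == toupper(target$a1[idx[present]])
  if (any(swap)) G[, swap] <- 2 - G[, swap]
  Xs <- scale(G, center = model$center[present],
              scale = model$scale[present])
  grex <- as.numeric(Xs %*% model$weights[present]) + model$intercept
  attr(grex, "missing_fraction") <- missing_fraction
  grex
}

#' GReX-phenotype association (TWAS step)
#'
#' Least squares of the phenotype on the imputed GReX plus covariates
#' (conventionally sex and age). Reports the GReX effect, its p-value and
#' the sign concordance with the gene's SMR effect when supplied.
#'
#' @param grex imputed GReX vector.
#' @param phenotype phenotype vector.
#' @param covariates optional covariate matrix.
#' @param b_smr optional SMR effect for sign-concordance.
#' @param gene,tissue,trait labels.
#' @return one-row data frame of class `twas_result`.
#' @export
twas_association <- function(grex, phenotype, covariates = NULL,
                             b_smr = NA_real_, gene = "gene",
                             tissue = "tissue", trait = "trait") {
  if (stats::sd(grex) == 0) stop("zero-variance GReX: association refused")
  X <- cbind(as.numeric(grex), covariates)
  colnames(X) <- c("grex", if (!is.null(covariates))
    paste0("cov", seq_len(ncol(X) - 1)))
  fit <- stats::lm(phenotype ~ X)
  sm <- summary(fit)$coefficients
  row <- 2L  # the GReX column follows the intercept
  est <- sm[row, "Estimate"]; p <- sm[row, "Pr(>|t|)"]
  out <- data.frame(
    gene = gene, tissue = tissue, trait = trait,
    effect = est, se = sm[row, "Std. Error"], p = p,
    sign_concordant = if (is.na(b_smr)) NA else sign(est) == sign(b_smr),
    stringsAsFactors = FALSE
  )
  class(out) <- c("twas_result", "data.frame")
  out
}
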