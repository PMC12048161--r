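#' Simulate an LD reference panel with block-structured linkage disequilibrium
#'
#' Generates diploid dosages (0/1/2) for `n_individuals` at
#' `sum(block_sizes)` variants arranged in LD blocks along one chromosome.
#' Each haplotype allele within a block copies a shared base haplotype with
#' probability `sqrt(within_block_corr)` and is drawn fresh at the block's
#' MAF otherwise, so alleles have exchangeable correlation exactly
#' `within_block_corr` inside a block (independent across blocks),
#' genotypes are in Hardy-Weinberg proportions, and LD is controlled
#' without full haplotype machinery. Variants in the same block share one
#' MAF (drawn per block from `maf_range`), as tightly linked variants do.
#'
#' @param n_individuals number of diploid individuals (rows of `G`).
#' @param block_sizes integer vector; number of variants per LD block.
#' @param within_block_corr latent correlation within a block, in [0, 1).
#' @param maf_range length-2 interval inside (0, 0.5]; per-variant target
#'   MAFs are drawn uniformly from it.
#' @param spacing base-pair distance between adjacent variants (default
#'   10 kb, so a 2 Mb LD-score window spans ~200 variants each side).
#' @param chrom chromosome label.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param store_R if `TRUE` (default) the variant-variant sample
#'   correlation matrix of `G` is computed and stored.
#'
#' @return An object of class `ld_panel`: a list with `variant_ids`,
#'   `chrom`, `pos` (1-based), `a1`, `a2`, `maf` (target MAF), `G`
#'   (n x m dosage matrix) and `R` (m x m sample correlation of `G`,
#'   or `NULL`).
#' @export
simulate_ld_panel <- function(n_individuals, block_sizes,
                              within_block_corr = 0.8,
                              maf_range = c(0.05, 0.5),
                              spacing = 10000L, chrom = "1",
                              seed = 1L, store_R = TRUE) {
  if (length(n_individuals) != 1L || !is.finite(n_individuals) || n_individuals < 2)
    stop("n_individuals must be a single integer >= 2")
  if (length(block_sizes) == 0L || any(block_sizes < 1))
    stop("block_sizes must be a non-empty vector of counts >= 1")
  if (within_block_corr < 0 || within_block_corr >= 1)
    stop("within_block_corr must lie in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval inside (0, 0.5]")
  n <- as.integer(n_individuals)
  block_sizes <- as.integer(block_sizes)
  m <- sum(block_sizes)
  set.seed(as.integer(seed))

  # one MAF per block: variants in strong LD share allele frequency, and
  # matching margins let the thresholded dosage correlation approach the
  # latent correlation
  maf <- rep(stats::runif(length(block_sizes), maf_range[1], maf_range[2]),
             times = block_sizes)

  # haplotype-copying model: within a block each variant's allele copies a
  # shared base haplotype with probability sqrt(rho) and is drawn fresh
  # otherwise, giving exchangeable allele correlation exactly rho (for the
  # block's common MAF); blocks are independent
  a <- sqrt(within_block_corr)
  block_id <- rep(seq_along(block_sizes), times = block_sizes)
  block_maf <- maf[!duplicated(block_id)]
  nb <- length(block_sizes)
  # allele is 1 with probability a + (1-a) maf when the base haplotype
  # carries it, (1-a) maf otherwise
  pm <- rep(maf, each = n)
  G <- matrix(0, n, m)
  for (hap in 1:2) {
    B <- matrix(stats::runif(n * nb), n) <
      matrix(block_maf, n, nb, byrow = TRUE)
    thr2 <- (1 - a) * pm + a * as.numeric(B[, block_id, drop = FALSE])
    G <- G + (stats::runif(n * m) < thr2)
  }
  # guard against monomorphic columns (possible at small n / extreme MAF)
  cs <- colSums(G)
  cs2 <- colSums(G * G)
  mono <- which(cs2 - cs^2 / n < .Machine$double.eps * n)
  for (j in mono) {
    i <- sample.int(n, 2L)
    G[i[1], j] <- 1L
    G[i[2], j] <- if (G[i[2], j] == 0L) 1L else G[i[2], j] - 1L
  }

  # unambiguous allele pairs only (no A/T, C/G), emulating post-QC data
  pairs <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                c("C", "A"), c("G", "A"), c("T", "C"), c("T", "G"))
  pick <- sample.int(length(pairs), m, replace = TRUE)
  a1 <- vapply(pairs[pick], `[`, "", 1L)
  a2 <- vapply(pairs[pick], `[`, "", 2L)

  panel <- structure(list(
    variant_ids = paste0("snp", seq_len(m)),
    chrom = rep(as.character(chrom), m),
    pos = as.integer(seq_len(m)) * as.integer(spacing),
    a1 = unname(a1), a2 = unname(a2),
    maf = maf,
    G = G,
    R = NULL,
    n = n,
    block_sizes = block_sizes
  ), class = "ld_panel")
  colnames(panel$G) <- panel$variant_ids
  panel <- cache_col_stats(panel)
  if (store_R) panel$R <- panel_correlation(panel)
  panel
}

# cache per-column dosage mean and sd (used by the marginal-statistic
# emitter and trait simulators; recomputed on subsetting)
cache_col_stats <- function(panel) {
  n <- nrow(panel$G)
  cs <- colSums(panel$G)
  cs2 <- colSums(panel$G * panel$G)
  panel$col_mean <- cs / n
  panel$col_sd <- sqrt(pmax(cs2 - cs^2 / n, 0) / (n - 1))
  panel
}

# BLAS-backed column correlation (stats::cor is a naive loop and far too
# slow at GWAS scale)
fast_cor <- function(A, B = NULL) {
  A <- as.matrix(A)
  As <- scale(A)
  n <- nrow(A)
  if (is.null(B)) {
    R <- crossprod(As) / (n - 1)
    R[cbind(seq_len(ncol(A)), seq_len(ncol(A)))] <- 1
    return(R)
  }
  crossprod(As, scale(as.matrix(B))) / (n - 1)
}

#' Sample correlation matrix of a panel's dosages
#'
#' @param panel an `ld_panel`.
#' @return m x m correlation matrix with unit diagonal.
#' @export
panel_correlation <- function(panel) {
  R <- fast_cor(panel$G)
  R <- (R + t(R)) / 2
  dimnames(R) <- list(panel$variant_ids, panel$variant_ids)
  R
}

#' Restrict a panel to a subset of individuals and/or variants
#'
#' Useful for building disjoint GWAS cohorts from one simulated genome, or
#' for extracting a cis window. `R` is recomputed on the subset.
#'
#' @param panel an `ld_panel`.
#' @param individuals row indices (default all).
#' @param variants variant indices or ids (default all).
#' @param store_R recompute the correlation matrix on the subset.
#' @return an `ld_panel`.
#' @export
subset_panel <- function(panel, individuals = NULL, variants = NULL,
                         store_R = TRUE) {
  if (is.null(individuals)) individuals <- seq_len(nrow(panel$G))
  if (is.null(variants)) variants <- seq_along(panel$variant_ids)
  if (is.character(variants)) variants <- match(variants, panel$variant_ids)
  out <- panel
  out$G <- panel$G[individuals, variants, drop = FALSE]
  for (f in c("variant_ids", "chrom", "pos", "a1", "a2", "maf"))
    out[[f]] <- panel[[f]][variants]
  out$n <- nrow(out$G)
  out$block_sizes <- NULL
  out <- cache_col_stats(out)
  out$R <- if (store_R) panel_correlation(out) else NULL
  out
}

#' @export
print.ld_panel <- function(x, ...) {
  cat("LD panel:", length(x$variant_ids), "variants,",
      x$n, "individuals,",
      if (is.null(x$R)) "R not stored" else "R stored", "\n")
  invisible(x)
}

validate_ld_panel <- function(panel, tol = 1e-8) {
  stopifnot(inherits(panel, "ld_panel"))
  m <- length(panel$variant_ids)
  for (f in c("chrom", "pos", "a1", "a2", "maf"))
    stopifnot(length(panel[[f]]) == m)
  stopifnot(all(panel$maf > 0), all(panel$maf <= 0.5))
  ord <- order(panel$chrom, panel$pos)
  stopifnot(!is.unsorted(ord), all(diff(panel$pos[ord]) != 0 | diff(as.integer(factor(panel$chrom[ord]))) != 0))
  if (!is.null(panel$R)) {
    stopifnot(max(abs(panel$R - t(panel$R))) < tol,
              max(abs(diag(panel$R) - 1)) < tol,
              max(abs(panel$R)) <= 1 + tol)
    if (!is.null(panel$G))
      stopifnot(max(abs(panel$R - panel_correlation(panel))) < tol)
  }
  invisible(TRUE)
}

# column-standardized dosages (mean 0, sd 1); cached pattern left to callers
standardize_dosages <- function(G) {
  Gs <- scale(G)
  attr(Gs, "scaled:center") <- NULL
  attr(Gs, "scaled:scale") <- NULL
  Gs
}
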