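logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log Bayes factors for a single effect given marginal effect estimates
# bhat with sampling variance s2 and prior effect variance V
.single_effect_lbf <- function(bhat, s2, V) {
  0.5 * log(s2 / (s2 + V)) + bhat^2 * V / (2 * s2 * (s2 + V))
}

#' Fine-map a locus by a sum of single effects (summary statistics)
#'
#' Iterative Bayesian single-effect decomposition of a locus: the signal is
#' modeled as a sum of at most `L` single effects, each a Bayesian
#' single-effect regression fit coordinate-wise on the z-scores
#' residualized for the other effects, with the LD matrix `R` supplying
#' the in-sample covariance (the usual sufficient-statistics
#' representation `X'X = n R`, `X'y = sqrt(n) z` with standardized X, y and
#' unit residual variance). Per-effect prior variances are estimated by
#' maximizing the single-effect likelihood (effects shrink to exactly null
#' when unsupported). For each non-null effect the 95% credible set is the
#' smallest prefix of descending-posterior variants reaching `coverage`;
#' sets with purity (minimum absolute within-set correlation) below
#' `purity_min` are discarded.
#'
#' @param z per-variant z-scores.
#' @param R LD (correlation) matrix, same order as `z`.
#' @param n GWAS sample size.
#' @param L maximum number of effects (default 10).
#' @param coverage credible-set coverage (default 0.95).
#' @param purity_min purity threshold (default 0.5).
#' @param max_iter,tol convergence controls (default 100, 1e-4 on the
#'   change in posterior-mean effects).
#' @param variant_ids optional ids carried into the credible sets.
#' @return object of class `finemap_fit`: `alpha` (L x m inclusion
#'   probabilities, each row summing to 1), `mu` (posterior means),
#'   `lbf` (L x m per-variant log Bayes factors), `V` (per-effect prior
#'   variance), `cs` (list of credible sets, variant indices), `cs_purity`,
#'   `pip`, `converged`.
#' @export
finemap_locus <- function(z, R, n, L = 10, coverage = 0.95,
                          purity_min = 0.5, max_iter = 100, tol = 1e-4,
                          variant_ids = NULL) {
  m <- length(z)
  if (!all(is.finite(z))) stop("z must be finite")
  if (!is.matrix(R) || nrow(R) != m || ncol(R) != m)
    stop("z and R dimensions must match")
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(m))
  L <- min(L, m)
  bhat_scale <- 1 / sqrt(n)       # marginal effects on the z scale / sqrt(n)
  s2 <- 1 / n
  zz <- z / sqrt(n)               # marginal bhat

  alpha <- matrix(1 / m, L, m)
  mu <- matrix(0, L, m)
  lbf <- matrix(0, L, m)
  V <- rep(0.04, L)               # initial prior variance, re-estimated
  B <- alpha * mu                  # L x m posterior mean effects
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    B_old <- B
    for (l in seq_len(L)) {
      b_other <- colSums(B[-l, , drop = FALSE])
      # residualized marginal estimates: bhat_j - (R b_other)_j
      bres <- zz - as.numeric(R %*% b_other)
      # estimate prior variance by maximizing the SER log-likelihood
      loglik <- function(lv) {
        v <- exp(lv)
        logsumexp(.single_effect_lbf(bres, s2, v)) - log(m)
      }
      opt <- stats::optimize(loglik, c(log(1e-8), log(4)), maximum = TRUE)
      V[l] <- if (opt$objective > 0) exp(opt$maximum) else 0
      if (V[l] > 0) {
        lbf[l, ] <- .single_effect_lbf(bres, s2, V[l])
        a <- exp(lbf[l, ] - max(lbf[l, ]))
        alpha[l, ] <- a / sum(a)
        post_var <- V[l] * s2 / (V[l] + s2)
        mu[l, ] <- post_var * bres / s2
      } else {
        lbf[l, ] <- 0
        alpha[l, ] <- 1 / m
        mu[l, ] <- 0
      }
      B[l, ] <- alpha[l, ] * mu[l, ]
    }
    if (max(abs(B - B_old)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("finemap_locus did not converge in ", max_iter, " iterations")

  active <- which(V > 0)
  cs <- list(); cs_purity <- numeric(0); cs_effect <- integer(0)
  for (l in active) {
    ord <- order(alpha[l, ], decreasing = TRUE)
    k <- which(cumsum(alpha[l, ord]) >= coverage)[1]
    set <- sort(ord[seq_len(k)])
    pur <- if (length(set) == 1) 1 else min(abs(R[set, set][upper.tri(R[set, set])]))
    if (pur >= purity_min) {
      key <- paste(set, collapse = ",")
      if (!key %in% vapply(cs, function(s) paste(s, collapse = ","), ""))
      {
        cs[[length(cs) + 1]] <- set
        cs_purity <- c(cs_purity, pur)
        cs_effect <- c(cs_effect, l)
      }
    }
  }
  if (length(cs)) names(cs) <- paste0("CS", seq_along(cs))
  pip <- 1 - apply(1 - alpha[active, , drop = FALSE], 2L, prod)
  structure(list(alpha = alpha, mu = mu, lbf = lbf, V = V,
                 cs = cs, cs_purity = cs_purity, cs_effect = cs_effect,
                 pip = pip, z = z, n = n, variant_ids = variant_ids,
                 coverage = coverage, purity_min = purity_min,
                 converged = converged, n_iter = iter),
            class = "finemap_fit")
}

#' @export
print.finemap_fit <- function(x, ...) {
  cat("Fine-mapping fit:", length(x$z), "variants,",
      length(x$cs), "credible set(s)",
      if (!x$converged) "[not converged]" else "", "\n")
  for (i in seq_along(x$cs))
    cat(sprintf("  %s (effect %d, purity %.2f): %s\n", names(x$cs)[i],
                x$cs_effect[i], x$cs_purity[i],
                paste(x$variant_ids[x$cs[[i]]], collapse = " ")))
  invisible(x)
}

#' Manhattan-style plot of a fine-mapped locus
#'
#' Plots per-variant -log10 marginal p-values with credible-set members
#' highlighted.
#'
#' @param x a `finemap_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.finemap_fit <- function(x, ...) {
  p <- 2 * stats::pnorm(-abs(x$z))
  graphics::plot(seq_along(x$z), -log10(p), pch = 16, col = "grey60",
                 xlab = "variant index", ylab = "-log10 p", ...)
  cols <- grDevices::rainbow(max(1, length(x$cs)))
  for (i in seq_along(x$cs))
    graphics::points(x$cs[[i]], -log10(p)[x$cs[[i]]], pch = 16,
                     col = cols[i])
  invisible(x)
}

#' Wakefield approximate log Bayes factors from effect estimates
#'
#' `lABF = 0.5 log(V/(V+W)) + z^2 W / (2 (V+W))` with `V = se^2` and prior
#' effect variance `W` (default 0.15^2, the quantitative-trait convention).
#'
#' @param beta,se per-variant effect estimates and standard errors.
#' @param W prior variance.
#' @return numeric vector of log Bayes factors.
#' @export
abf_from_ss <- function(beta, se, W = 0.15^2) {
  V <- se^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + z2 * W / (2 * (V + W))
}

.lbf_list <- function(fit) {
  if (inherits(fit, "finemap_fit")) {
    eff <- unique(fit$cs_effect)
    if (length(eff) == 0) return(list())
    lapply(eff, function(l) fit$lbf[l, ])
  } else if (is.numeric(fit)) {
    list(as.numeric(fit))
  } else stop("fit must be a finemap_fit or a numeric lABF vector")
}

#' Pairwise colocalization of decomposed signals
#'
#' For each pair of single effects (one per trait), combines the
#' per-variant log Bayes factors into posteriors over the five
#' colocalization hypotheses: H0 no association, H1/H2 one trait only,
#' H3 two distinct causal variants, H4 a shared causal variant. With
#' per-variant priors `p1`, `p2` and `p12`,
#' `PH1 : p1 sum_j BF1_j`, `PH3 : p1 p2 (S1 S2 - S12)`,
#' `PH4 : p12 S12` where `S12 = sum_j BF1_j BF2_j`. Colocalization is
#' called when `PPH4 > PPH3`.
#'
#' @param fit1,fit2 `finemap_fit` objects (effects with credible sets are
#'   used) or plain numeric lABF vectors (single-signal mode, e.g. from
#'   [abf_from_ss()]).
#' @param p1,p2,p12 per-variant prior probabilities (defaults 1e-4, 1e-4,
#'   1e-5).
#' @param labels optional `c(trait1, trait2)` labels.
#' @return data frame of class `coloc_result`, one row per effect pair:
#'   `effect1`, `effect2`, `pph0..pph4`, `colocalized`; priors stored as
#'   attributes.
#' @export
coloc_pair <- function(fit1, fit2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       labels = c("trait1", "trait2")) {
  l1 <- .lbf_list(fit1); l2 <- .lbf_list(fit2)
  e1 <- if (inherits(fit1, "finemap_fit")) unique(fit1$cs_effect) else 1L
  e2 <- if (inherits(fit2, "finemap_fit")) unique(fit2$cs_effect) else 1L
  if (length(l1) == 0 || length(l2) == 0) {
    out <- data.frame(trait1 = character(), trait2 = character(),
                      effect1 = integer(), effect2 = integer(),
                      pph0 = numeric(), pph1 = numeric(), pph2 = numeric(),
                      pph3 = numeric(), pph4 = numeric(),
                      colocalized = logical())
    class(out) <- c("coloc_result", "data.frame")
    return(out)
  }
  rows <- list()
  for (i in seq_along(l1)) for (j in seq_along(l2)) {
    b1 <- l1[[i]]; b2 <- l2[[j]]
    if (length(b1) != length(b2))
      stop("traits must share one variant universe")
    ls1 <- logsumexp(b1)
    ls2 <- logsumexp(b2)
    ls12 <- logsumexp(b1 + b2)
    lh <- c(
      h0 = 0,
      h1 = log(p1) + ls1,
      h2 = log(p2) + ls2,
      h3 = log(p1) + log(p2) + ls1 + ls2 +
        log1p(-pmin(exp(ls12 - ls1 - ls2), 1 - 1e-12)),
      h4 = log(p12) + ls12
    )
    post <- exp(lh - logsumexp(lh))
    rows[[length(rows) + 1]] <- data.frame(
      trait1 = labels[1], trait2 = labels[2],
      effect1 = e1[i], effect2 = e2[j],
      pph0 = post[1], pph1 = post[2], pph2 = post[3],
      pph3 = post[4], pph4 = post[5],
      colocalized = post[5] > post[4],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "priors") <- c(p1 = p1, p2 = p2, p12 = p12)
  class(out) <- c("coloc_result", "data.frame")
  out
}

#' Assemble the trait colocalization network
#'
#' Nodes are trait signals in three classes (`expression`, `focal`,
#' `endo`); edges are colocalization instances (PPH4 > PPH3).
#' Near-duplicate endophenotypes — same category with pairwise genetic
#' correlation above `prune_rg` — are collapsed to a representative node
#' sized by member count. Triangles with one node of each class are
#' enumerated as cliques (strong evidence); trios connected by exactly two
#' of the three edges are flagged weak.
#'
#' @param edges data frame with columns `node1`, `node2`, `class1`,
#'   `class2` (values in expression/focal/endo), `pph3`, `pph4`.
#' @param rg optional symmetric named matrix of genetic correlations among
#'   endo nodes.
#' @param categories optional named vector: category per endo node.
#' @param prune_rg pruning threshold (default 0.9).
#' @return object of class `trait_network`: `nodes`, `edges` (with
#'   `colocalized`), `cliques`, `weak_trios`.
#' @export
build_network <- function(edges, rg = NULL, categories = NULL,
                          prune_rg = 0.9) {
  need <- c("node1", "node2", "class1", "class2", "pph3", "pph4")
  stopifnot(all(need %in% names(edges)))

  # collapse near-duplicate endophenotype nodes (union-find)
  endo_nodes <- unique(c(edges$node1[edges$class1 == "endo"],
                         edges$node2[edges$class2 == "endo"]))
  rep_of <- stats::setNames(endo_nodes, endo_nodes)
  if (!is.null(rg) && length(endo_nodes) > 1) {
    parent <- stats::setNames(seq_along(endo_nodes), endo_nodes)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(endo_nodes)) for (j in seq_len(i - 1L)) {
      a <- endo_nodes[i]; b <- endo_nodes[j]
      if (!is.null(categories) &&
          !identical(unname(categories[a]), unname(categories[b]))) next
      if (a %in% rownames(rg) && b %in% rownames(rg) &&
          abs(rg[a, b]) > prune_rg)
        parent[find(i)] <- find(j)
    }
    roots <- vapply(seq_along(endo_nodes), find, 0L)
    rep_of <- stats::setNames(endo_nodes[roots], endo_nodes)
  }
  group_size <- table(rep_of)

  e <- edges
  e$node1 <- ifelse(e$class1 == "endo", rep_of[e$node1], e$node1)
  e$node2 <- ifelse(e$class2 == "endo", rep_of[e$node2], e$node2)
  e$colocalized <- e$pph4 > e$pph3
  # deduplicate parallel edges, keeping the strongest colocalization
  key <- paste(pmin(e$node1, e$node2), pmax(e$node1, e$node2))
  e <- e[order(key, -e$pph4), ]
  e <- e[!duplicated(paste(pmin(e$node1, e$node2), pmax(e$node1, e$node2))), ]
  rownames(e) <- NULL

  nodes <- unique(data.frame(
    id = c(e$node1, e$node2),
    class = c(e$class1, e$class2),
    stringsAsFactors = FALSE))
  nodes$size <- ifelse(nodes$class == "endo",
                       as.integer(group_size[nodes$id]), 1L)

  kept <- e[e$colocalized, , drop = FALSE]
  adj <- function(a, b) any((kept$node1 == a & kept$node2 == b) |
                            (kept$node1 == b & kept$node2 == a))
  expr_nodes <- nodes$id[nodes$class == "expression"]
  focal_nodes <- nodes$id[nodes$class == "focal"]
  endo_reps <- nodes$id[nodes$class == "endo"]
  cliques <- list(); weak <- list()
  for (ex in expr_nodes) for (fo in focal_nodes) for (en in endo_reps) {
    k <- adj(ex, fo) + adj(ex, en) + adj(fo, en)
    row <- data.frame(expression = ex, focal = fo, endo = en,
                      stringsAsFactors = FALSE)
    if (k == 3) cliques[[length(cliques) + 1]] <- row
    else if (k == 2) weak[[length(weak) + 1]] <- row
  }
  empty <- data.frame(expression = character(), focal = character(),
                      endo = character(), stringsAsFactors = FALSE)
  structure(list(
    nodes = nodes, edges = e,
    cliques = if (length(cliques)) do.call(rbind, cliques) else empty,
    weak_trios = if (length(weak)) do.call(rbind, weak) else empty,
    prune_rg = prune_rg
  ), class = "trait_network")
}

#' @export
print.trait_network <- function(x, ...) {
  cat("Trait network:", nrow(x$nodes), "nodes,",
      sum(x$edges$colocalized), "colocalization edge(s),",
      nrow(x$cliques), "clique(s),", nrow(x$weak_trios),
      "weak trio(s)\n")
  invisible(x)
}

#' Intersect the three credible sets of a colocalization clique
#'
#' Takes one credible set per trait (by default the effect participating
#' in the PPH4-maximal pairwise colocalization), intersects them, and
#' annotates each member with its LD to the lead variant — the smallest
#' GWAS p-value among genome-wide-significant members. Members with
#' `R^2 > r2_tag` to the lead are flagged high-LD. An empty intersection
#' demotes the clique.
#'
#' @param fit_expr,fit_focal,fit_endo `finemap_fit` objects on a shared
#'   variant universe.
#' @param panel `ld_panel` for LD (same variant universe).
#' @param gwas_p per-variant GWAS p-values for the focal trait (same
#'   order).
#' @param r2_tag high-LD threshold (default 0.5).
#' @param gw_sig genome-wide significance for the lead (default 5e-8).
#' @param cs_expr,cs_focal,cs_endo optional credible-set indices (into
#'   `fit$cs`) overriding the automatic PPH4-maximal choice.
#' @return list of class `cs_intersection`: `table` (id, pos, gwas_p,
#'   r2_to_lead, high_ld, is_lead), `demoted`, `reason`.
#' @export
intersect_credible_sets <- function(fit_expr, fit_focal, fit_endo, panel,
                                    gwas_p, r2_tag = 0.5, gw_sig = 5e-8,
                                    cs_expr = NULL, cs_focal = NULL,
                                    cs_endo = NULL) {
  # anchor on the expression signal: pick the expression effect with the
  # strongest colocalization against either trait, then for each trait the
  # effect that best colocalizes with that expression effect
  pick_expr <- function() {
    if (length(fit_expr$cs) == 0) return(NA_integer_)
    if (!is.null(cs_expr)) return(cs_expr)
    if (length(fit_expr$cs) == 1) return(1L)
    best <- 1L; best_p <- -Inf
    for (oth in list(fit_focal, fit_endo)) {
      if (length(oth$cs) == 0) next
      cc <- coloc_pair(fit_expr, oth)
      for (i in seq_along(fit_expr$cs)) {
        ci <- cc[cc$effect1 == fit_expr$cs_effect[i], , drop = FALSE]
        if (nrow(ci) && max(ci$pph4) > best_p) {
          best_p <- max(ci$pph4); best <- i
        }
      }
    }
    best
  }
  i_e <- pick_expr()
  pick_vs_expr <- function(fit, forced) {
    if (length(fit$cs) == 0) return(NA_integer_)
    if (!is.null(forced)) return(forced)
    if (length(fit$cs) == 1 || is.na(i_e)) return(1L)
    cc <- coloc_pair(fit_expr, fit)
    cc <- cc[cc$effect1 == fit_expr$cs_effect[i_e], , drop = FALSE]
    if (nrow(cc) == 0) return(1L)
    match(cc$effect2[which.max(cc$pph4)], fit$cs_effect)
  }
  i_f <- pick_vs_expr(fit_focal, cs_focal)
  i_n <- pick_vs_expr(fit_endo, cs_endo)
  if (anyNA(c(i_e, i_f, i_n)))
    return(structure(list(table = NULL, demoted = TRUE,
                          reason = "a trait has no credible set"),
                     class = "cs_intersection"))
  sets <- list(fit_expr$cs[[i_e]], fit_focal$cs[[i_f]], fit_endo$cs[[i_n]])
  inter <- Reduce(intersect, sets)
  if (length(inter) == 0)
    return(structure(list(table = NULL, demoted = TRUE,
                          reason = "empty credible-set intersection"),
                     class = "cs_intersection"))
  inter <- sort(inter)
  pvals <- gwas_p[inter]
  sig <- pvals <= gw_sig
  lead_i <- if (any(sig)) inter[sig][which.min(pvals[sig])]
            else inter[which.min(pvals)]
  R <- if (!is.null(panel$R)) panel$R else panel_correlation(panel)
  r2 <- R[inter, lead_i]^2
  tab <- data.frame(
    id = panel$variant_ids[inter],
    chrom = panel$chrom[inter], pos = panel$pos[inter],
    gwas_p = pvals, r2_to_lead = r2, high_ld = r2 > r2_tag,
    is_lead = inter == lead_i,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(table = tab, demoted = FALSE,
                 reason = if (any(sig)) NA_character_
                          else "no genome-wide significant member",
                 cs_used = c(expression = i_e, focal = i_f, endo = i_n)),
            class = "cs_intersection")
}

#' @export
print.cs_intersection <- function(x, ...) {
  if (x$demoted) cat("Credible-set intersection: demoted (", x$reason, ")\n")
  else {
    cat("Credible-set intersection:", nrow(x$table), "variant(s)\n")
    print(x$table, digits = 3)
  }
  invisible(x)
}
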