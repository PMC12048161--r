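#' Build a pipeline configuration
#'
#' Returns the nested configuration driving [run_pipeline()]: synthetic
#' genome and cohort sizes, all stage thresholds (summary-stat MAF/INFO
#' filters, PPA and HEIDI cutoffs, GReX holdout filter, colocalization
#' priors, delta-score flag, rg pruning, LD tagging, permutation and Monte
#' Carlo draw counts) and stage toggles. Values are validated against
#' their documented ranges. The configuration round-trips losslessly
#' through YAML ([write_config()] / [read_config()]).
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param sim,thresholds,perm,mc,finemap,coloc,grex,epi,stages named lists
#'   overriding individual defaults (see the source for the full set).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = list(), thresholds = list(),
                            perm = list(), mc = list(), finemap = list(),
                            coloc = list(), grex = list(), epi = list(),
                            stages = list()) {
  merge <- function(defaults, user) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    seed = as.integer(seed),
    sim = merge(list(
      n_eqtl = 700L, n_gwas = 4000L, n_blocks = 40L, block_size = 25L,
      within_block_corr = 0.7, maf_range = c(0.1, 0.5), spacing = 10000L,
      n_genes = 8L, n_pleiotropic = 2L, h2_cis = 0.4,
      h2_shared_per_variant = 0.02
    ), sim),
    thresholds = merge(list(
      maf_min = 0.01, info_min = 0.95, ppa = 0.5, heidi_alpha = 0.05,
      grex_r_min = 0.1, delta_svm = 2, rg_prune = 0.9, r2_tag = 0.5,
      instrument_p = 5e-8, gw_sig = 5e-8
    ), thresholds),
    perm = merge(list(n_perm = 10000L, K_list = c(1L, 5L, 10L)), perm),
    mc = merge(list(n_draws = 50000L), mc),
    finemap = merge(list(L = 10L, coverage = 0.95, purity_min = 0.5), finemap),
    coloc = merge(list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5), coloc),
    grex = merge(list(cis = 1e6, alpha = 0.5, train_fraction = 0.8), grex),
    epi = merge(list(l = 6L, k = 4L, n_pos = 800L, n_peaks = 2000L,
                     peak_length = 60L, embed_prob = 1, gc = 0.41), epi),
    stages = merge(list(rg = TRUE, smr = TRUE, perm = TRUE, grex = TRUE,
                        coloc = TRUE, epi = TRUE, motif = TRUE), stages)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
validate_config <- function(config) {
  th <- config$thresholds
  in01 <- function(x) x >= 0 && x <= 1
  checks <- c(
    "ppa must lie in [0, 1]" = in01(th$ppa),
    "heidi_alpha must lie in [0, 1]" = in01(th$heidi_alpha),
    "maf_min must lie in [0, 0.5]" = th$maf_min >= 0 && th$maf_min <= 0.5,
    "info_min must lie in [0, 1]" = in01(th$info_min),
    "rg_prune must lie in [0, 1]" = in01(th$rg_prune),
    "r2_tag must lie in [0, 1]" = in01(th$r2_tag),
    "delta_svm threshold must be non-negative" = th$delta_svm >= 0,
    "grex_r_min must lie in [-1, 1]" = abs(th$grex_r_min) <= 1,
    "n_perm must be positive" = config$perm$n_perm >= 1,
    "n_draws must be positive" = config$mc$n_draws >= 1,
    "coverage must lie in (0, 1]" = config$finemap$coverage > 0 &&
      config$finemap$coverage <= 1,
    "coloc priors must lie in (0, 1)" =
      all(unlist(config$coloc) > 0 & unlist(config$coloc) < 1)
  )
  if (!all(checks))
    stop("invalid configuration: ",
         paste(names(checks)[!checks], collapse = "; "))
  invisible(config)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = raw$seed)
  for (f in setdiff(names(raw), "seed")) cfg[[f]] <- raw[[f]]
  validate_config(cfg)
  cfg
}

stage_tsv <- function(df, path, config, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pleioscan %s", as.character(utils::packageVersion("pleioscan"))),
    sprintf("# stage: %s", stage),
    sprintf("# seed: %d", config$seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the synthetic end-to-end pipeline
#'
#' Builds a synthetic genome with known ground truth (LD-block genotypes;
#' `n_pleiotropic` genes whose single cis causal variant also drives the
#' focal trait and the endophenotype; null genes with private eQTLs) and
#' runs the stages in dependency order: marginal summary statistics,
#' genetic correlation, SMR + HEIDI gene discovery, circular-permutation
#' overlap, GReX training / TWAS confirmation, fine-mapping +
#' colocalization + network + credible-set intersection, accessibility
#' scoring of the candidate variants (the true causal variant creates the
#' embedded motif core), and motif disruption calls. Stage outputs are
#' written as TSV (with a provenance header) under `out_dir` when given;
#' reruns with the same config are deterministic.
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional output directory (created if needed).
#' @return list of class `pipeline_run` with per-stage results and
#'   `truth` (ground-truth record).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name, stage) {
    if (!is.null(out_dir))
      stage_tsv(df, file.path(out_dir, name), config, stage)
  }
  sm <- config$sim
  th <- config$thresholds
  res <- list(config = config)

  ## ---- synthesize genome, cohorts and ground truth ----
  # heterogeneous LD blocks (genes live in the even, full-size blocks;
  # odd blocks are small spacers) so LD scores vary across the genome,
  # which the LD-score regression needs for identification
  n_all <- sm$n_eqtl + sm$n_gwas
  spacer <- rep(c(1L, 5L, 2L, 10L), length.out = ceiling(sm$n_blocks / 2))
  block_sizes <- integer(sm$n_blocks)
  block_sizes[seq(2L, sm$n_blocks, by = 2L)] <- sm$block_size
  block_sizes[seq(1L, sm$n_blocks, by = 2L)] <-
    spacer[seq_len(length(seq(1L, sm$n_blocks, by = 2L)))]
  genome <- simulate_ld_panel(
    n_all, block_sizes,
    within_block_corr = sm$within_block_corr, maf_range = sm$maf_range,
    spacing = sm$spacing, seed = config$seed, store_R = FALSE)
  eqtl_panel <- subset_panel(genome, individuals = seq_len(sm$n_eqtl))
  gwas_panel <- subset_panel(genome,
                             individuals = sm$n_eqtl + seq_len(sm$n_gwas))
  m <- length(genome$variant_ids)
  gene_blocks <- seq(2L, by = 2L, length.out = sm$n_genes)
  block_start <- cumsum(c(0L, block_sizes)) + 1L
  gene_center <- block_start[gene_blocks] + ceiling(sm$block_size / 2) - 1L
  gene_tss <- genome$pos[gene_center]
  genes <- paste0("gene", seq_len(sm$n_genes))
  pleio <- seq_len(sm$n_pleiotropic)
  causal_idx <- gene_center  # per-gene cis causal variant

  set.seed(config$seed + 1L)
  # focal and endophenotype built from the pleiotropic genes' causal
  # variants (opposite-sign effects: increased focal, reduced endo size)
  Xc <- standardize_dosages(gwas_panel$G[, causal_idx[pleio], drop = FALSE])
  b_focal <- sqrt(sm$h2_shared_per_variant) * rep(1, length(pleio))
  b_endo <- -b_focal
  h2_tot <- sm$h2_shared_per_variant * length(pleio)
  g_focal <- as.numeric(Xc %*% b_focal)
  g_endo <- as.numeric(Xc %*% b_endo)
  y_focal <- as.numeric(scale(g_focal + sqrt(1 - h2_tot) * stats::rnorm(sm$n_gwas)))
  y_endo <- as.numeric(scale(g_endo + sqrt(1 - h2_tot) * stats::rnorm(sm$n_gwas)))

  expr <- lapply(seq_len(sm$n_genes), function(g)
    simulate_cis_expression(eqtl_panel, gene_tss[g], cis_window = 2e6,
                            h2_cis = sm$h2_cis,
                            causal_ids = genome$variant_ids[causal_idx[g]],
                            seed = config$seed + 10L + g))
  truth <- list(
    genes = genes, gene_tss = gene_tss,
    pleiotropic_genes = genes[pleio],
    causal_ids = genome$variant_ids[causal_idx],
    shared_causal_ids = genome$variant_ids[causal_idx[pleio]])
  res$truth <- truth

  gwas_focal <- compute_marginal_stats(gwas_panel, y_focal,
                                       maf_min = th$maf_min,
                                       info_min = th$info_min)
  gwas_endo <- compute_marginal_stats(gwas_panel, y_endo,
                                      maf_min = th$maf_min,
                                      info_min = th$info_min)
  eqtl_ss <- lapply(seq_len(sm$n_genes), function(g) {
    cis <- which(abs(eqtl_panel$pos - gene_tss[g]) <= 2e6)
    compute_marginal_stats(subset_panel(eqtl_panel, variants = cis,
                                        store_R = FALSE),
                           expr[[g]]$expression,
                           maf_min = th$maf_min, info_min = th$info_min)
  })
  emit(gwas_focal, "gwas_focal.tsv", "simulate")
  emit(gwas_endo, "gwas_endo.tsv", "simulate")

  ## ---- genetic correlation ----
  if (config$stages$rg) {
    scores <- compute_ld_scores(gwas_panel, window = 2e6)
    n_blocks <- max(2L, min(50L, floor(m / (3L * sm$block_size))))
    res$rg <- cross_trait_ldsc(gwas_focal, gwas_endo, scores,
                               n_blocks = n_blocks)
    emit(data.frame(trait = "endo", rg = res$rg$rg, se = res$rg$se$rg,
                    p = res$rg$p_value), "rg.tsv", "rg")
  }

  ## ---- SMR + HEIDI ----
  if (config$stages$smr) {
    smr_rows <- list()
    for (g in seq_len(sm$n_genes)) for (tr in c("focal", "endo")) {
      gw <- if (tr == "focal") gwas_focal else gwas_endo
      # HEIDI: eQTL-side LD from the eQTL cohort, GWAS-side LD from the
      # GWAS cohort (see the methods vignette)
      row <- run_smr(eqtl_ss[[g]], gw, eqtl_panel, gene = genes[g],
                     tissue = "tissue1", trait = tr,
                     p_instrument = th$instrument_p, ppa_min = th$ppa,
                     heidi_alpha = th$heidi_alpha,
                     panel_gwas = gwas_panel)
      if (!is.null(row)) smr_rows[[length(smr_rows) + 1]] <- row
    }
    res$smr <- do.call(rbind, smr_rows)
    res$pleiotropic <- discover_pleiotropic_genes(res$smr, "focal")
    emit(res$smr, "smr_results.tsv", "smr")
    emit(res$pleiotropic, "pleiotropic_genes.tsv", "smr")
  }

  ## ---- circular permutation overlap ----
  if (config$stages$perm && !is.null(res$smr)) {
    passing <- res$smr[res$smr$pass, , drop = FALSE]
    label_a <- genes %in% passing$gene[passing$trait == "focal"]
    label_b <- genes %in% passing$gene[passing$trait != "focal"]
    res$perm <- consistency_scan(label_a, label_b,
                                 K_list = pmin(config$perm$K_list,
                                               length(genes)),
                                 n_perm = config$perm$n_perm,
                                 seed = config$seed + 100L)
    emit(res$perm, "overlap_permutation.tsv", "perm")
  }

  ## ---- GReX / TWAS ----
  if (config$stages$grex && !is.null(res$pleiotropic) &&
      nrow(res$pleiotropic) > 0) {
    set.seed(config$seed + 200L)
    covar <- cbind(sex = stats::rbinom(sm$n_gwas, 1, 0.5),
                   age = stats::rnorm(sm$n_gwas, 60, 7))
    twas_rows <- list(); models <- list()
    for (gname in res$pleiotropic$gene) {
      g <- match(gname, genes)
      model <- train_grex(eqtl_panel, expr[[g]]$expression, gene_tss[g],
                          cis = config$grex$cis, gene = gname,
                          alpha = config$grex$alpha,
                          train_fraction = config$grex$train_fraction,
                          r_min = th$grex_r_min,
                          seed = config$seed + 300L + g)
      models[[gname]] <- model
      if (is.null(model) || !model$pass) next
      grex <- impute_grex(model, gwas_panel)
      for (tr in c("focal", "endo")) {
        y <- if (tr == "focal") y_focal else y_endo
        bs <- res$smr$b_smr[res$smr$gene == gname & res$smr$trait == tr]
        twas_rows[[length(twas_rows) + 1]] <-
          twas_association(grex, y, covar,
                           b_smr = if (length(bs)) bs[1] else NA,
                           gene = gname, trait = tr)
      }
    }
    res$grex_models <- models
    res$twas <- if (length(twas_rows)) do.call(rbind, twas_rows) else NULL
    if (!is.null(res$twas)) emit(res$twas, "twas.tsv", "grex")
  }

  ## ---- fine-mapping, colocalization, network, intersection ----
  if (config$stages$coloc && !is.null(res$pleiotropic) &&
      nrow(res$pleiotropic) > 0) {
    fm <- config$finemap
    edge_rows <- list(); inters <- list(); fits <- list()
    for (gname in res$pleiotropic$gene) {
      g <- match(gname, genes)
      cis <- which(abs(gwas_panel$pos - gene_tss[g]) <= config$grex$cis)
      loc_gwas <- subset_panel(gwas_panel, variants = cis)
      loc_eqtl <- subset_panel(eqtl_panel, variants = cis)
      ids <- loc_gwas$variant_ids
      ze <- eqtl_ss[[g]]$z[match(ids, eqtl_ss[[g]]$id)]
      zf <- gwas_focal$z[match(ids, gwas_focal$id)]
      zn <- gwas_endo$z[match(ids, gwas_endo$id)]
      fit_e <- finemap_locus(ze, loc_eqtl$R, sm$n_eqtl, L = fm$L,
                             coverage = fm$coverage,
                             purity_min = fm$purity_min,
                             variant_ids = ids)
      fit_f <- finemap_locus(zf, loc_gwas$R, sm$n_gwas, L = fm$L,
                             coverage = fm$coverage,
                             purity_min = fm$purity_min,
                             variant_ids = ids)
      fit_n <- finemap_locus(zn, loc_gwas$R, sm$n_gwas, L = fm$L,
                             coverage = fm$coverage,
                             purity_min = fm$purity_min,
                             variant_ids = ids)
      fits[[gname]] <- list(expression = fit_e, focal = fit_f,
                            endo = fit_n)
      pr <- config$coloc
      pairs <- list(
        c1 = coloc_pair(fit_e, fit_f, pr$p1, pr$p2, pr$p12,
                        labels = c(paste0(gname, "_expr"), "focal")),
        c2 = coloc_pair(fit_e, fit_n, pr$p1, pr$p2, pr$p12,
                        labels = c(paste0(gname, "_expr"), "endo")),
        c3 = coloc_pair(fit_f, fit_n, pr$p1, pr$p2, pr$p12,
                        labels = c("focal", "endo")))
      cls <- list(c1 = c("expression", "focal"),
                  c2 = c("expression", "endo"),
                  c3 = c("focal", "endo"))
      for (nm in names(pairs)) {
        cc <- pairs[[nm]]
        if (nrow(cc) == 0) next
        cc <- cc[which.max(cc$pph4), , drop = FALSE]
        edge_rows[[length(edge_rows) + 1]] <- data.frame(
          node1 = cc$trait1, node2 = cc$trait2,
          class1 = cls[[nm]][1], class2 = cls[[nm]][2],
          pph3 = cc$pph3, pph4 = cc$pph4, stringsAsFactors = FALSE)
      }
      ci <- intersect_credible_sets(fit_e, fit_f, fit_n, loc_gwas,
                                    2 * stats::pnorm(-abs(zf)),
                                    r2_tag = th$r2_tag,
                                    gw_sig = th$gw_sig)
      inters[[gname]] <- ci
    }
    res$finemap <- fits
    edges <- do.call(rbind, edge_rows)
    res$network <- build_network(edges, prune_rg = th$rg_prune)
    res$intersections <- inters
    emit(res$network$edges, "network_edges.tsv", "coloc")
    itabs <- lapply(names(inters), function(g)
      if (!inters[[g]]$demoted) cbind(gene = g, inters[[g]]$table))
    itab <- do.call(rbind, itabs)
    if (!is.null(itab)) emit(itab, "candidate_variants.tsv", "coloc")
  }

  ## ---- epigenetic fine-mapping ----
  cand <- NULL
  if (!is.null(res$intersections)) {
    ok <- !vapply(res$intersections, `[[`, TRUE, "demoted")
    if (any(ok))
      cand <- unique(unlist(lapply(res$intersections[ok],
                                   function(x) x$table$id)))
  }
  if (config$stages$epi && length(cand) > 0) {
    ep <- config$epi
    acc_motif <- accessibility_example_pwm()
    peaks <- simulate_peaks(ep$n_peaks, ep$peak_length, acc_motif,
                            embed_prob = ep$embed_prob, gc = ep$gc,
                            seed = config$seed + 400L)
    negs <- background_sequences(peaks$sequences, seed = config$seed + 401L)
    model <- train_accessibility_model(peaks$sequences, negs, l = ep$l,
                                       k = ep$k, n_pos = ep$n_pos,
                                       cell_type = "synthetic_cell",
                                       seed = config$seed + 402L)
    # synthetic contig: each candidate variant gets a background context;
    # the true shared causal variant's alternate allele completes the
    # embedded motif core (ref AGAA -> alt GGAA)
    set.seed(config$seed + 403L)
    w <- 2L * (ep$l - 1L) + 1L
    spacing_ctx <- w + 20L
    bases <- c("A", "C", "G", "T")
    ctg <- sample(bases, length(cand) * spacing_ctx + 40L, replace = TRUE)
    vdf <- data.frame(id = cand, contig = "locus",
                      pos = 20L + (seq_along(cand) - 1L) * spacing_ctx +
                        ep$l,
                      ref = NA_character_, alt = NA_character_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(vdf))) {
      p <- vdf$pos[i]
      if (vdf$id[i] %in% truth$shared_causal_ids) {
        # reference carries AGAA where the embedded motif has its GGAA
        # core; the alternate allele completes the consensus site
        site <- strsplit(pwm_consensus(acc_motif), "")[[1]]
        site[4] <- "A"
        ctg[(p - 3L):(p + 6L)] <- site
        vdf$ref[i] <- "A"; vdf$alt[i] <- "G"
      } else {
        vdf$ref[i] <- ctg[p]
        vdf$alt[i] <- sample(setdiff(bases, ctg[p]), 1L)
      }
    }
    contig <- stats::setNames(paste(ctg, collapse = ""), "locus")
    res$epi <- list(model = model,
                    effects = score_candidates(vdf, list(model), contig,
                                               threshold = th$delta_svm),
                    variants = vdf, contig = contig)
    emit(res$epi$effects$table, "variant_effects.tsv", "epi")

    ## ---- motif analysis ----
    if (config$stages$motif) {
      flagged <- names(which(res$epi$effects$any_cell_type))
      collection <- list(ets_example_pwm(), acc_motif)
      calls <- list()
      for (vid in flagged) {
        v <- vdf[vdf$id == vid, ]
        wmax <- max(vapply(collection, `[[`, 0L, "width"))
        ctx_lo <- v$pos - wmax
        ctx_hi <- v$pos + wmax
        ctx <- substr(contig, ctx_lo, ctx_hi)
        for (pw in collection)
          calls[[paste(vid, pw$id)]] <-
            cbind(variant = vid,
                  classify_variant(v$ref, v$alt, ctx,
                                   v$pos - ctx_lo + 1L, pw))
      }
      if (length(calls)) {
        res$motif <- rank_tfs(do.call(rbind, calls))
        emit(res$motif, "motif_calls.tsv", "motif")
      }
    }
  }

  if (!is.null(out_dir)) {
    write_config(config, file.path(out_dir, "config.yaml"))
    manifest <- list(
      package = "pleioscan",
      version = as.character(utils::packageVersion("pleioscan")),
      seed = config$seed,
      stages_run = names(Filter(isTRUE, config$stages)),
      outputs = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  class(res) <- "pipeline_run"
  res
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pleioscan pipeline run (seed", x$config$seed, ")\n")
  if (!is.null(x$rg))
    cat(sprintf("  rg(focal, endo) = %.3f (p = %.3g)\n", x$rg$rg,
                x$rg$p_value))
  if (!is.null(x$pleiotropic))
    cat("  pleiotropic genes:",
        paste(x$pleiotropic$gene, collapse = ", "), "\n")
  if (!is.null(x$network))
    cat("  colocalization cliques:", nrow(x$network$cliques), "\n")
  if (!is.null(x$epi))
    cat("  variants flagged by accessibility model:",
        sum(x$epi$effects$any_cell_type, na.rm = TRUE), "\n")
  invisible(x)
}
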