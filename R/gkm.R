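gkm_patterns <- function(l, k) {
  if (k > l) stop("k (informative positions) cannot exceed word length l")
  asplit(utils::combn(l, k), 2L)
}

# gapped k-mer words of one sequence, counted on both strands (a sequence
# and its reverse complement give identical feature vectors). Words are the
# dotted l-mers, e.g. "AC.G.T"; windows containing N are skipped.
gkm_words <- function(sequence, l, k, patterns = gkm_patterns(l, k)) {
  s <- toupper(sequence)
  if (nchar(s) < l) return(character(0))
  combined <- c(strsplit(s, "")[[1]], rep("N", l),
                strsplit(revcomp(s), "")[[1]])
  W <- length(combined) - l + 1L
  idx <- outer(0:(l - 1L), seq_len(W), "+")
  mat <- matrix(combined[idx], nrow = l)
  valid <- colSums(mat == "N") == 0
  if (!any(valid)) return(character(0))
  mat <- mat[, valid, drop = FALSE]
  unlist(lapply(patterns, function(p) {
    do.call(paste0, lapply(seq_len(l), function(j)
      if (j %in% p) mat[j, ] else "."))
  }), use.names = FALSE)
}

#' Gapped k-mer feature counts of a DNA sequence
#'
#' Counts all gapped k-mers — length-`l` windows with `l - k` wildcard
#' positions — over the sequence and its reverse complement (strand
#' canonicalization), skipping windows that contain `N`.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param l word length.
#' @param k informative (non-wildcard) positions, `k <= l`.
#' @return named integer vector of counts (dotted-word feature names);
#'   empty for sequences shorter than `l`.
#' @export
extract_features <- function(sequence, l = 6, k = 4) {
  w <- gkm_words(sequence, l, k)
  if (length(w) == 0) return(stats::setNames(integer(0), character(0)))
  r <- rle(sort(w))
  stats::setNames(r$lengths, r$values)
}

# sparse n_sequences x n_features count matrix
gkm_feature_matrix <- function(sequences, l, k,
                               patterns = gkm_patterns(l, k),
                               vocabulary = NULL) {
  per_seq <- lapply(sequences, function(s) {
    w <- gkm_words(s, l, k, patterns)
    if (length(w) == 0) return(list(v = character(0), n = integer(0)))
    r <- rle(sort(w))
    list(v = r$values, n = r$lengths)
  })
  vs <- lapply(per_seq, `[[`, "v")
  vocab <- if (is.null(vocabulary)) unique(unlist(vs, use.names = FALSE))
  else vocabulary
  jj <- match(unlist(vs, use.names = FALSE), vocab)
  ii <- rep.int(seq_along(per_seq), lengths(vs))
  xx <- unlist(lapply(per_seq, `[[`, "n"), use.names = FALSE)
  keep <- !is.na(jj)
  ii <- ii[keep]; jj <- jj[keep]; xx <- xx[keep]
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(sequences), length(vocab)),
                       dimnames = list(names(sequences), vocab))
}

auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train a per-cell-type sequence model of chromatin accessibility
#'
#' Linear classifier (regularized logistic regression by default, or a
#' linear SVM when e1071 is available) on gapped k-mer features of peak
#' versus background sequences. Mirrors the training protocol of
#' deltaSVM-style accessibility models: a cell type is trained only when
#' at least `n_pos` peaks are available, exactly `n_pos` are subsampled,
#' and a holdout AUROC is recorded.
#'
#' @param positives named character vector of peak sequences.
#' @param negatives background sequences (e.g. from
#'   [background_sequences()]); at least as many as positives used.
#' @param l,k gapped k-mer parameters (defaults 6 and 4, a desk-scale
#'   setting; see the methods vignette).
#' @param n_pos required/subsampled number of positives (default 5000).
#' @param holdout_fraction held out for the AUROC (default 0.2).
#' @param method `"logistic"` (glmnet ridge) or `"svm"` (e1071 linear).
#' @param cell_type label.
#' @param seed integer seed (subsampling, split, CV folds).
#' @return object of class `accessibility_model`, or `NULL` (with a
#'   message) when fewer than `n_pos` positives are available.
#' @export
train_accessibility_model <- function(positives, negatives, l = 6, k = 4,
                                      n_pos = 5000, holdout_fraction = 0.2,
                                      method = c("logistic", "svm"),
                                      cell_type = "cell_type", seed = 1L) {
  method <- match.arg(method)
  if (length(positives) < n_pos) {
    message("cell type '", cell_type, "' skipped: ", length(positives),
            " < ", n_pos, " open chromatin regions")
    return(NULL)
  }
  if (length(negatives) < n_pos)
    stop("need at least n_pos negative sequences")
  set.seed(as.integer(seed))
  pos <- sample(positives, n_pos)
  neg <- sample(negatives, n_pos)
  seqs <- c(pos, neg)
  y <- rep(c(1L, 0L), each = n_pos)
  n_hold <- round(holdout_fraction * n_pos)
  hold <- c(sample.int(n_pos, n_hold), n_pos + sample.int(n_pos, n_hold))
  Xall <- gkm_feature_matrix(seqs, l, k)
  Xtr <- Xall[-hold, , drop = FALSE]
  Xte <- Xall[hold, , drop = FALSE]
  if (method == "logistic") {
    fit <- glmnet::cv.glmnet(Xtr, y[-hold], family = "binomial", alpha = 0,
                             nfolds = 4)
    co <- as.numeric(stats::coef(fit, s = "lambda.min"))
    intercept <- co[1]; w <- co[-1]
  } else {
    if (!requireNamespace("e1071", quietly = TRUE))
      stop("method = 'svm' requires the e1071 package")
    sv <- e1071::svm(as.matrix(Xtr), factor(y[-hold]), kernel = "linear",
                     scale = FALSE)
    w <- as.numeric(t(sv$coefs) %*% sv$SV)
    if (sv$labels[1] == 0) w <- -w
    intercept <- -sv$rho
  }
  scores <- as.numeric(Xte %*% w)
  model <- structure(list(
    cell_type = cell_type, l = l, k = k,
    features = colnames(Xall), weights = w, intercept = intercept,
    method = method, n_pos = n_pos, n_neg = n_pos,
    holdout_auroc = auroc(scores, y[hold] == 1L), seed = seed
  ), class = "accessibility_model")
  model
}

#' @export
print.accessibility_model <- function(x, ...) {
  cat(sprintf(
    "Accessibility model [%s]: l = %d, k = %d, %d features, holdout AUROC = %.3f\n",
    x$cell_type, x$l, x$k, length(x$features), x$holdout_auroc))
  invisible(x)
}

#' Linear gapped k-mer score of a sequence
#'
#' Sum over gapped k-mer features of count times weight (the intercept is
#' excluded: variant scoring uses score differences, where it cancels).
#'
#' @param model an `accessibility_model`.
#' @param sequence DNA string.
#' @return numeric score.
#' @export
score_sequence <- function(model, sequence) {
  f <- extract_features(sequence, model$l, model$k)
  j <- match(names(f), model$features)
  keep <- !is.na(j)
  sum(model$weights[j[keep]] * f[keep])
}

#' deltaSVM-style variant effect score
#'
#' Difference between the model scores of the alternate- and
#' reference-allele windows centered on the variant. For a linear model
#' this equals the sum of per-feature weight differences over the k-mer
#' windows overlapping the variant, so edits outside the
#' `2(l - 1) + 1`-base window cannot change the score.
#'
#' @param model an `accessibility_model`.
#' @param ref_window,alt_window equal-length windows centered on the
#'   variant, identical except at the variant position.
#' @return numeric delta score (alt minus ref).
#' @export
delta_svm <- function(model, ref_window, alt_window) {
  if (nchar(ref_window) != nchar(alt_window))
    stop("ref and alt windows of a SNV must have equal length")
  score_sequence(model, alt_window) - score_sequence(model, ref_window)
}

#' Score candidate variants across all cell-type models
#'
#' Extracts a `pos +/- (l - 1)` window around each variant from the
#' supplied contig sequences, substitutes the alternate allele, and
#' computes the delta score per model. Variants too close to a contig edge
#' are skipped with a message.
#'
#' @param variants data frame with columns `id`, `contig`, `pos` (1-based
#'   within the contig), `ref`, `alt`.
#' @param models list of `accessibility_model`s.
#' @param sequences named character vector of contig sequences.
#' @param threshold flag magnitude (default 2).
#' @return object of class `variant_effect_table`: long `table`
#'   (variant x cell type with `delta_svm` and `flagged`) and per-variant
#'   `any_cell_type` flags.
#' @export
score_candidates <- function(variants, models, sequences, threshold = 2) {
  models <- Filter(Negate(is.null), models)
  if (length(models) == 0) stop("no trained models supplied")
  rows <- list()
  for (vi in seq_len(nrow(variants))) {
    v <- variants[vi, ]
    contig <- sequences[[v$contig]]
    if (is.null(contig)) { message("variant ", v$id, ": unknown contig, skipped"); next }
    for (mod in models) {
      w <- mod$l - 1L
      if (v$pos - w < 1 || v$pos + w > nchar(contig)) {
        message("variant ", v$id, ": window out of contig bounds, skipped")
        break
      }
      ref_win <- substr(contig, v$pos - w, v$pos + w)
      if (substr(ref_win, w + 1L, w + 1L) != toupper(v$ref))
        warning("variant ", v$id, ": contig base differs from stated ref")
      alt_win <- ref_win
      substr(alt_win, w + 1L, w + 1L) <- toupper(v$alt)
      d <- delta_svm(mod, ref_win, alt_win)
      rows[[length(rows) + 1]] <- data.frame(
        id = v$id, cell_type = mod$cell_type, ref = v$ref, alt = v$alt,
        delta_svm = d, flagged = abs(d) > threshold,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), cell_type = character(), ref = character(),
               alt = character(), delta_svm = numeric(), flagged = logical())
  any_flag <- tapply(tab$flagged, tab$id, any)
  structure(list(table = tab,
                 any_cell_type = any_flag[unique(tab$id)],
                 threshold = threshold),
            class = "variant_effect_table")
}

#' @export
print.variant_effect_table <- function(x, ...) {
  cat("Variant effect table:", length(unique(x$table$id)), "variant(s) x",
      length(unique(x$table$cell_type)), "cell type(s);",
      sum(x$any_cell_type, na.rm = TRUE),
      "variant(s) flagged (|delta| >", x$threshold, ")\n")
  invisible(x)
}
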