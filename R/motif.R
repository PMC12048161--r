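#' Construct a position weight matrix
#'
#' @param mat 4 x w matrix of per-position base probabilities or counts,
#'   rows in A, C, G, T order. Counts are normalized per column.
#' @param id motif identifier.
#' @param tf transcription factor name.
#' @param family TF family annotation (optional).
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param pseudocount added per base before log-odds (motif databases
#'   contain zeros), default 1e-3.
#' @return an object of class `pwm` with the probability matrix, the
#'   background and the derived log2-odds matrix.
#' @export
pwm <- function(mat, id = "motif", tf = id, family = NA_character_,
                background = rep(0.25, 4), pseudocount = 1e-3) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0))
    stop("background must be positive frequencies summing to 1")
  p <- sweep(mat, 2L, colSums(mat), "/")
  p <- sweep(p + pseudocount, 2L, colSums(p + pseudocount), "/")
  lo <- log2(p / background)
  rownames(p) <- rownames(lo) <- c("A", "C", "G", "T")
  structure(list(id = id, tf = tf, family = family, prob = p,
                 background = background, log_odds = lo,
                 pseudocount = pseudocount,
                 width = ncol(p)), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "(", x$tf, "), width", x$width,
      ", consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param x a `pwm`.
#' @return character string of length `x$width`.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$prob)[apply(x$prob, 2L, which.max)], collapse = "")
}

#' Log-odds score of one window against a PWM
#'
#' Sum over positions of `log2(p(base) / bg(base))` using the
#' pseudocount-adjusted probabilities stored in the `pwm`. Windows
#' containing `N` score `NA` (placement undefined).
#'
#' @param window character string, same length as the motif.
#' @param pwm a `pwm`.
#' @return numeric log2-odds score (NA if the window contains N).
#' @export
score_window <- function(window, pwm) {
  b <- strsplit(toupper(window), "")[[1]]
  if (length(b) != pwm$width)
    stop("window length must equal motif width")
  i <- match(b, c("A", "C", "G", "T"))
  if (anyNA(i)) return(NA_real_)
  sum(pwm$log_odds[cbind(i, seq_along(i))])
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Classify a variant's effect on a motif (gain / loss, strong)
#'
#' Scans every placement of the motif overlapping the variant, on both
#' strands, under the reference and the alternate allele. Ref and alt are
#' compared at the same placement — the one scoring best under either
#' allele — avoiding placement-shift artifacts. The effect is a gain if
#' the alt score exceeds the ref score and a loss otherwise; it is
#' "strong" when the two log-odds scores have opposite signs (binding
#' site effectively created or destroyed).
#'
#' @param ref,alt single reference / alternate bases.
#' @param context character string of sequence surrounding the variant;
#'   must extend at least `width - 1` bases on both sides.
#' @param pos_in_context 1-based position of the variant within `context`.
#' @param pwm a `pwm`.
#' @return one-row data frame of class `disruption_call`: motif id, tf,
#'   family, strand, placement offset, ref/alt scores, delta, effect
#'   (`gain`/`loss`/`none`) and `strong` flag.
#' @export
classify_variant <- function(ref, alt, context, pos_in_context, pwm) {
  context <- toupper(context)
  w <- pwm$width
  L <- nchar(context)
  if (pos_in_context < w || pos_in_context > L - w + 1)
    stop("insufficient context around the variant for motif width ", w)
  if (substr(context, pos_in_context, pos_in_context) != toupper(ref))
    stop("context does not carry the stated reference allele")
  alt_context <- context
  substr(alt_context, pos_in_context, pos_in_context) <- toupper(alt)

  starts <- (pos_in_context - w + 1):pos_in_context
  best <- list(score = -Inf)
  for (s in starts) {
    win_ref <- substr(context, s, s + w - 1)
    win_alt <- substr(alt_context, s, s + w - 1)
    for (strand in c("+", "-")) {
      wr <- if (strand == "+") win_ref else revcomp(win_ref)
      wa <- if (strand == "+") win_alt else revcomp(win_alt)
      sr <- score_window(wr, pwm)
      sa <- score_window(wa, pwm)
      if (is.na(sr) || is.na(sa)) next
      top <- max(sr, sa)
      if (top > best$score)
        best <- list(score = top, ref = sr, alt = sa, start = s,
                     strand = strand)
    }
  }
  if (!is.finite(best$score)) stop("no scorable placement (N in context?)")
  delta <- best$alt - best$ref
  effect <- if (toupper(ref) == toupper(alt) || delta == 0) "none"
            else if (delta > 0) "gain" else "loss"
  strong <- effect != "none" && (sign(best$ref) * sign(best$alt) < 0)
  out <- data.frame(
    motif = pwm$id, tf = pwm$tf, family = pwm$family,
    strand = best$strand, start = best$start,
    score_ref = best$ref, score_alt = best$alt, delta = delta,
    effect = effect, strong = strong, stringsAsFactors = FALSE
  )
  class(out) <- c("disruption_call", "data.frame")
  out
}

#' Rank motif disruption calls across a motif collection
#'
#' Strong calls first, ordered by absolute score change; ties broken
#' deterministically by motif id.
#'
#' @param calls data frame of `classify_variant` rows (rbind-ed).
#' @return the calls reordered, with a `rank` column.
#' @export
rank_tfs <- function(calls) {
  if (nrow(calls) == 0) stop("at least one call required")
  ord <- order(!calls$strong, -abs(calls$delta), calls$motif)
  out <- calls[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a JASPAR-format PFM file
#'
#' Parses the conventional JASPAR text layout: a `>ID NAME` header line
#' followed by four rows of counts, either bare numbers or in the
#' `A [ 1 2 3 ]` bracket style. Several motifs per file are supported.
#'
#' @param path file path.
#' @param background,pseudocount passed to [pwm()].
#' @return list of `pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 1e-3) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no JASPAR headers ('>') found in ", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    id <- toks[1]
    tf <- if (length(toks) > 1) toks[2] else toks[1]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) < 4) stop("motif ", id, ": expected 4 count rows")
    rows <- lapply(body[1:4], function(ln) {
      ln <- gsub("^[ACGTacgt]?\\s*\\[", "", ln)
      ln <- gsub("\\]", "", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop("motif ", id, ": ragged count rows")
    out[[i]] <- pwm(do.call(rbind, rows), id = id, tf = tf,
                    background = background, pseudocount = pseudocount)
  }
  names(out) <- vapply(out, function(p) p$id, "")
  out
}

#' Write PWMs in JASPAR bracket format
#'
#' The stored (pseudocount-adjusted) probabilities are back-transformed to
#' pre-pseudocount weights, so a write/read cycle with the same
#' pseudocount reproduces the PWM exactly.
#'
#' @param pwms list of `pwm` objects.
#' @param path file path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id, " ", p$tf), con)
    pc <- if (is.null(p$pseudocount)) 1e-3 else p$pseudocount
    cnt <- p$prob * (1 + 4 * pc) - pc
    for (i in 1:4)
      writeLines(sprintf("%s [ %s ]", c("A", "C", "G", "T")[i],
                         paste(format(cnt[i, ], digits = 17),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Synthetic ETS-family example PWM (GGAA core)
#'
#' A small hand-built PWM emulating an ETS-class binding preference with
#' the canonical GGAA core flanked by weakly informative positions. It is
#' synthetic (not derived from any motif database) and exists for worked
#' examples and tests.
#'
#' @param id,tf labels.
#' @return a `pwm` of width 10 whose consensus contains the `GGAA` core.
#' @export
ets_example_pwm <- function(id = "SYNTH-ETS", tf = "ETS-like") {
  # Decisive GGAA core (near-zero off-consensus counts, as in real ETS
  # PFMs) framed by weakly informative flanks. The weak columns stay in
  # [0.2, 0.3], so their total log-odds contribution lies in
  # (-2, +1.6) bits at any placement: at the core-aligned placement a
  # single core mismatch (~ -8 bits against ~ +5.8 from the remaining
  # core) forces a negative score and a full core (+7.7) a positive one.
  # Creating or destroying GGAA is then a "strong" event unless the
  # flanking sequence happens to complete a competing core across the
  # variant.
  # positions:     1     2     3      4      5      6      7     8     9    10
  # consensus:     C     A     C      G      G      A      A     G     T     G
  A <- c(0.24, 0.30, 0.24, 0.000, 0.000, 1.000, 1.000, 0.22, 0.24, 0.24)
  C <- c(0.30, 0.24, 0.30, 0.000, 0.000, 0.000, 0.000, 0.24, 0.22, 0.22)
  G <- c(0.24, 0.24, 0.24, 1.000, 1.000, 0.000, 0.000, 0.30, 0.24, 0.30)
  T <- c(0.22, 0.22, 0.22, 0.000, 0.000, 0.000, 0.000, 0.24, 0.30, 0.24)
  pwm(rbind(A, C, G, T), id = id, tf = tf, family = "ETS")
}

#' Synthetic high-information accessibility motif
#'
#' A width-10 PWM, sharp at every position (consensus `CACGGAAGTG`,
#' an ETS-like site), used to embed a discriminative signal in synthetic
#' open-chromatin peaks for accessibility-model training. Synthetic — not
#' derived from any motif database.
#'
#' @param id,tf labels.
#' @return a `pwm` of width 10.
#' @export
accessibility_example_pwm <- function(id = "SYNTH-ACC", tf = "ACC-like") {
  cons <- c("C", "A", "C", "G", "G", "A", "A", "G", "T", "G")
  mat <- matrix(0.03, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  mat[cbind(match(cons, rownames(mat)), 1:10)] <- 0.91
  pwm(mat, id = id, tf = tf, family = "ETS")
}
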