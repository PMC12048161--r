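#' Simulate open-chromatin peak sequences with embedded motif sites
#'
#' Positive peak sequences are i.i.d. background at the requested GC
#' content; with probability `embed_prob` each carries one motif site,
#' sampled per position from the PWM's base probabilities, at a uniformly
#' random offset. Peaks are laid out head-to-tail on a synthetic contig,
#' with BED intervals in 0-based half-open convention.
#'
#' @param n_peaks number of peaks.
#' @param peak_length peak width in bases (must be at least the motif
#'   width when embedding).
#' @param embedded_pwm a [pwm()] or `NULL` for pure background.
#' @param embed_prob probability a peak carries a site, in [0, 1].
#' @param gc GC content of the background, in (0, 1).
#' @param gap bases between consecutive peaks on the contig.
#' @param contig contig name for the BED intervals.
#' @param seed integer seed.
#' @return list with `sequences` (named character vector), `bed` (data
#'   frame `chrom, start, end, name`), and `truth` (data frame per peak:
#'   `embedded` flag, 1-based `site_start` within the peak, `site_seq`).
#' @export
simulate_peaks <- function(n_peaks, peak_length = 300L, embedded_pwm = NULL,
                           embed_prob = 1, gc = 0.41, gap = 200L,
                           contig = "chrS", seed = 1L) {
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  if (embed_prob < 0 || embed_prob > 1) stop("embed_prob must lie in [0, 1]")
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
  if (!is.null(embedded_pwm)) {
    stopifnot(inherits(embedded_pwm, "pwm"))
    if (peak_length < embedded_pwm$width)
      stop("peak_length must be at least the motif width")
  }
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  bg <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  seqs <- character(n_peaks)
  embedded <- logical(n_peaks)
  site_start <- rep(NA_integer_, n_peaks)
  site_seq <- rep(NA_character_, n_peaks)
  for (i in seq_len(n_peaks)) {
    s <- sample(bases, peak_length, replace = TRUE, prob = bg)
    if (!is.null(embedded_pwm) && stats::runif(1) < embed_prob) {
      w <- embedded_pwm$width
      site <- vapply(seq_len(w), function(j)
        sample(bases, 1L, prob = embedded_pwm$prob[, j]), "")
      off <- sample.int(peak_length - w + 1L, 1L)
      s[off:(off + w - 1L)] <- site
      embedded[i] <- TRUE
      site_start[i] <- off
      site_seq[i] <- paste(site, collapse = "")
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- paste0("peak", seq_len(n_peaks))
  starts0 <- (seq_len(n_peaks) - 1L) * (peak_length + gap)
  bed <- data.frame(chrom = contig, start = starts0,
                    end = starts0 + peak_length, name = names(seqs),
                    stringsAsFactors = FALSE)
  truth <- data.frame(name = names(seqs), embedded = embedded,
                      site_start = site_start, site_seq = site_seq,
                      stringsAsFactors = FALSE)
  list(sequences = seqs, bed = bed, truth = truth)
}

#' Background (negative) sequences matched to a peak set
#'
#' Default is a per-sequence dinucleotide shuffle (preserves dinucleotide
#' composition via a random Eulerian-style reassembly of the observed
#' transitions); alternatively GC-matched i.i.d. background.
#'
#' @param sequences character vector of peak sequences.
#' @param method `"dinucleotide"` or `"gc_matched"`.
#' @param seed integer seed.
#' @return character vector of the same lengths, named `neg*`.
#' @export
background_sequences <- function(sequences,
                                 method = c("dinucleotide", "gc_matched"),
                                 seed = 1L) {
  method <- match.arg(method)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  out <- vapply(sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (method == "gc_matched") {
      gc <- mean(ch %in% c("G", "C"))
      bg <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
      paste(sample(bases, length(ch), replace = TRUE, prob = bg),
            collapse = "")
    } else {
      dinuc_shuffle(ch)
    }
  }, "", USE.NAMES = FALSE)
  names(out) <- paste0("neg", seq_along(out))
  out
}

# random walk on the observed first-order transition counts, started at the
# original first base; falls back to remaining-pool sampling at dead ends
dinuc_shuffle <- function(ch) {
  n <- length(ch)
  if (n < 3) return(paste(ch, collapse = ""))
  trans <- table(factor(ch[-n], levels = c("A", "C", "G", "T")),
                 factor(ch[-1], levels = c("A", "C", "G", "T")))
  cnt <- matrix(as.numeric(trans), 4, 4,
                dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    row <- cnt[cur, ]
    if (sum(row) == 0) {
      pool <- rowSums(cnt)
      if (sum(pool) == 0) { # exhausted; keep remaining original order
        out[i:n] <- ch[i:n]
        break
      }
      nxt <- sample(names(pool), 1L, prob = pool)
      # no transition consumed (chain restart)
    } else {
      nxt <- sample(colnames(cnt), 1L, prob = row)
      cnt[cur, nxt] <- cnt[cur, nxt] - 1
    }
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
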