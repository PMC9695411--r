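#' Default analysis windows per pattern
#'
#' Epileptic spikes use a `[-1, +1]` s epoch with a `[-1, -0.5]` s baseline;
#' the longer patterns use `[-2, +2]` s with a `[-2, -1]` s baseline.
#'
#' @param label annotation label.
#' @return two-element numeric vector (seconds relative to onset).
#' @export
default_window <- function(label) {
  if (label == "ES") c(-1, 1) else c(-2, 2)
}

#' @rdname default_window
#' @export
default_baseline <- function(label) {
  if (label == "ES") c(-1, -0.5) else c(-2, -1)
}

#' Epoch a signal around annotated events
#'
#' Cuts one trial per annotation of the requested label whose epoch (window
#' plus an alignment pad) lies fully inside the recording and whose window
#' overlaps no artifact annotation. Trials are cut on the signal's sample
#' grid.
#'
#' @param signal a [sampled_signal] (typically at 1 kHz).
#' @param annotations an [annotation_table].
#' @param label which pattern to epoch.
#' @param window_s `c(pre, post)` window in seconds relative to onset
#'   (default per [default_window]).
#' @param pad_s extra samples kept on each side so trials can later be
#'   re-cut after alignment shifts (must be >= the alignment `max_lag_s`).
#' @return An object of class `trial_matrix`: `data` (trials x time, padded),
#'   `times_s` (axis of the unpadded window), `onsets_s`, `shifts_s`,
#'   `window_s`, `pad_s`, `fs_hz`, `label`.
#' @export
epoch <- function(signal, annotations, label, window_s = NULL, pad_s = 0.35) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (is.null(window_s)) window_s <- default_window(label)
  stopifnot(length(window_s) == 2, window_s[1] < window_s[2])
  fs <- signal$fs_hz
  rows <- annotations_with_label(annotations, label)
  art <- annotations_with_label(annotations, "artifact")
  n <- length(signal$samples)
  i_pre <- round((window_s[1] - pad_s) * fs)
  i_post <- round((window_s[2] + pad_s) * fs)
  len <- i_post - i_pre + 1L
  onsets <- numeric(0); keep_rows <- list()
  for (j in seq_len(nrow(rows))) {
    on <- rows$start_s[j]
    i0 <- round((on - signal$t0_s) * fs) + 1L  # sample index of onset
    lo <- i0 + i_pre; hi <- i0 + i_post
    if (lo < 1L || hi > n) next
    if (nrow(art) && any(intervals_overlap(on + window_s[1], on + window_s[2],
                                           art$start_s, art$end_s))) next
    keep_rows[[length(keep_rows) + 1L]] <- signal$samples[lo:hi]
    onsets <- c(onsets, on)
  }
  if (!length(keep_rows)) {
    warning(sprintf("no usable '%s' events; returning empty trial matrix",
                    label))
    data <- matrix(numeric(0), nrow = 0, ncol = len)
  } else {
    data <- do.call(rbind, keep_rows)
  }
  structure(list(
    data = data, fs_hz = fs, label = label, window_s = window_s,
    pad_s = pad_s, onsets_s = onsets,
    shifts_s = rep(0, length(onsets)),
    times_s = seq(round(window_s[1] * fs), round(window_s[2] * fs)) / fs,
    converged = NA), class = "trial_matrix")
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf("<trial_matrix> %s: %d trials, window [%g, %g] s @ %g Hz (pad %g s)\n",
              x$label, nrow(x$data), x$window_s[1], x$window_s[2], x$fs_hz,
              x$pad_s))
  invisible(x)
}

# Number of pad samples on each side of the analysis window
tm_pad_samples <- function(tm) round(tm$pad_s * tm$fs_hz)

# The unpadded window block of the trial data
tm_window_data <- function(tm) {
  p <- tm_pad_samples(tm)
  m <- length(tm$times_s)
  tm$data[, p + seq_len(m), drop = FALSE]
}

# Pearson correlation of a zero-mean template against all segments of x
# starting at positions `starts` (1-based), via one FFT cross-correlation.
xcorr_pearson <- function(x, tmpl_c, starts) {
  m <- length(tmpl_c); n <- length(x)
  nfft <- stats::nextn(n + m, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  Tm <- stats::fft(c(tmpl_c, numeric(nfft - m)))
  r <- Re(stats::fft(X * Conj(Tm), inverse = TRUE)) / nfft
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  sx <- cs[starts + m] - cs[starts]
  sx2 <- cs2[starts + m] - cs2[starts]
  denom <- sqrt(pmax(sx2 - sx^2 / m, 0)) * sqrt(sum(tmpl_c^2))
  num <- r[starts]
  out <- rep(0, length(starts))
  ok <- denom > 0
  out[ok] <- num[ok] / denom[ok]
  out
}

#' Align trials by maximizing cross-correlation with the trial average
#'
#' Iterative template alignment: the template is the current grand-average
#' time course over the analysis window; each trial is shifted to the integer
#' lag (within `+/- max_lag_s`) that maximizes its Pearson correlation
#' (mean-subtracted) with the template, the average is recomputed, and the
#' procedure repeats until no shift changes by more than `tol_samples` or
#' `max_iter` is reached. Ties in the correlation maximum resolve to the
#' smallest `|lag|`. The returned trials are re-cut at the corrected onsets
#' (the pad is consumed), with the applied shift recorded per trial.
#'
#' @param tm a [trial_matrix] from [epoch] with `pad_s >= max_lag_s`.
#' @param max_lag_s maximum allowed onset correction (s).
#' @param max_iter maximum template iterations.
#' @param tol_samples convergence tolerance on the largest shift change.
#' @return A [trial_matrix] with `pad_s = 0`, corrected `onsets_s`, applied
#'   `shifts_s`, and a logical `converged` flag.
#' @export
align_trials <- function(tm, max_lag_s = NULL, max_iter = 10,
                         tol_samples = 1) {
  stopifnot(inherits(tm, "trial_matrix"))
  if (is.null(max_lag_s)) max_lag_s <- if (tm$label == "ES") 0.15 else 0.3
  if (max_lag_s > tm$pad_s)
    stop("pad_s of the trial matrix must be >= max_lag_s")
  win_len <- diff(tm$window_s)
  if (max_lag_s >= win_len / 2)
    stop("max_lag_s must be smaller than half the window")
  ntr <- nrow(tm$data)
  if (ntr < 2) stop("alignment requires at least 2 trials")
  fs <- tm$fs_hz
  L <- round(max_lag_s * fs)
  p <- tm_pad_samples(tm)
  m <- length(tm$times_s)
  lags <- -L:L
  # tie-break order: smallest |lag|, negative before positive at equal |lag|
  tie_order <- order(abs(lags), lags)
  shifts <- rep(0L, ntr)
  converged <- FALSE
  cut_rows <- function(sh)
    t(vapply(seq_len(ntr), function(i)
      tm$data[i, p + sh[i] + seq_len(m)], numeric(m)))
  for (it in seq_len(max_iter)) {
    tmpl <- colMeans(cut_rows(shifts))
    tmpl_c <- tmpl - mean(tmpl)
    new_shifts <- vapply(seq_len(ntr), function(i) {
      cc <- xcorr_pearson(tm$data[i, ], tmpl_c, starts = p + 1L + lags)
      best <- tie_order[which.max(cc[tie_order])]
      lags[best]
    }, 0L)
    delta <- max(abs(new_shifts - shifts))
    shifts <- new_shifts
    if (delta <= tol_samples) { converged <- TRUE; break }
  }
  out <- tm
  out$data <- cut_rows(shifts)
  out$pad_s <- 0
  out$shifts_s <- shifts / fs
  out$onsets_s <- tm$onsets_s + shifts / fs
  out$converged <- converged
  out
}

#' Export aligned onsets as an annotation table
#'
#' @param tm an aligned [trial_matrix].
#' @param channel_id channel name for the exported rows.
#' @return An [annotation_table] with the corrected onsets (zero-length
#'   events).
#' @export
aligned_annotations <- function(tm, channel_id = "u1") {
  annotation_table(label = rep(tm$label, length(tm$onsets_s)),
                   channel_id = channel_id,
                   start_s = tm$onsets_s, end_s = tm$onsets_s)
}
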