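#' Hanning-taper time-frequency representation of aligned trials
#'
#' Short-time spectral power via a Hanning-tapered sliding window stepped
#' every `step_s` (default 5 ms). Power at each requested frequency is the
#' squared modulus of the tapered discrete Fourier coefficient, averaged
#' across trials (the trial-average TFR; per-trial normalization is available
#' in [baseline_normalize]). Windows extending past the epoch are dropped (no
#' padding), so the time axis of the map is trimmed by half a window at each
#' end. The frequency grid defaults to multiples of the taper's resolution
#' `1/window_s` covering 60-200 Hz (2.5 Hz bins for the 400 ms window, 5 Hz
#' bins for the 200 ms window).
#'
#' @param tm an aligned [trial_matrix] (pad consumed).
#' @param window_s taper length in seconds: 0.2 for epileptic spikes, 0.4 for
#'   the longer patterns (default chosen from the pattern label).
#' @param freqs_hz analysis frequencies (must lie in (0, 500]).
#' @param step_s window step (default 0.005 s).
#' @param keep_trials keep the per-trial power array (needed for per-trial
#'   normalization).
#' @return An object of class `tfr_map`: `power` (freq x time, raw),
#'   `freqs_hz`, `times_s` (window centers), `window_s`, `label`,
#'   `normalized = FALSE`.
#' @export
compute_tfr <- function(tm, window_s = NULL, freqs_hz = NULL, step_s = 0.005,
                        keep_trials = FALSE) {
  stopifnot(inherits(tm, "trial_matrix"))
  if (is.null(window_s)) window_s <- if (tm$label == "ES") 0.2 else 0.4
  fs <- tm$fs_hz
  dat <- tm_window_data(tm)
  ntr <- nrow(dat); nt <- ncol(dat)
  wlen <- round(window_s * fs)
  if (wlen > nt) stop("taper window longer than the trial epoch")
  if (is.null(freqs_hz)) {
    df <- 1 / window_s
    freqs_hz <- seq(ceiling(60 / df) * df, 200, by = df)
  }
  if (any(freqs_hz <= 0 | freqs_hz > 500))
    stop("analysis frequencies must lie in (0, 500] Hz")
  step <- max(1L, round(step_s * fs))
  half <- floor(wlen / 2)
  centers <- seq(half + 1L, nt - (wlen - half - 1L), by = step)
  if (!length(centers)) stop("epoch too short for the requested window")
  taper <- 0.5 * (1 - cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1)))
  tt <- (seq_len(wlen) - 1) / fs
  basis <- exp(-2i * pi * outer(tt, freqs_hz))          # wlen x nf
  basis <- basis * taper
  idx <- outer(centers - half, seq_len(wlen) - 1L, `+`)  # ncenter x wlen
  nf <- length(freqs_hz); nc <- length(centers)
  pow <- matrix(0, nf, nc)
  trials <- if (keep_trials) array(0, c(ntr, nf, nc)) else NULL
  for (i in seq_len(ntr)) {
    seg <- matrix(dat[i, idx], nc, wlen)
    P <- t(Mod(seg %*% basis)^2)                         # nf x ncenter
    pow <- pow + P
    if (keep_trials) trials[i, , ] <- P
  }
  pow <- pow / max(1L, ntr)
  structure(list(power = pow, freqs_hz = freqs_hz,
                 times_s = tm$times_s[centers], window_s = window_s,
                 step_s = step_s, label = tm$label, normalized = FALSE,
                 baseline_window_s = NULL, trials = trials),
            class = "tfr_map")
}

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf("<tfr_map> %s: %d freqs (%g-%g Hz) x %d times, %s\n",
              x$label, length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_s),
              if (x$normalized) "% change vs baseline" else "raw power"))
  invisible(x)
}

#' Express a TFR as percentage change from baseline
#'
#' Per frequency `f`: `100 * (P(f,t) - B(f)) / B(f)` where `B(f)` is the mean
#' raw power over the baseline window (`[-1, -0.5]` s for epileptic spikes,
#' `[-2, -1]` s for the longer patterns, by default). By construction the
#' baseline window's own mean percentage change is 0 at every frequency.
#'
#' @param tfr a raw-power `tfr_map`.
#' @param baseline_window_s `c(from, to)` in seconds relative to onset.
#' @param per_trial normalize each trial's power by the trial-average baseline
#'   before averaging (only if the TFR kept trials); default normalizes the
#'   trial-average map.
#' @return A `tfr_map` with `power` in percent change and `normalized = TRUE`.
#' @export
baseline_normalize <- function(tfr, baseline_window_s = NULL,
                               per_trial = FALSE) {
  stopifnot(inherits(tfr, "tfr_map"))
  if (tfr$normalized) stop("TFR is already baseline-normalized")
  if (is.null(baseline_window_s))
    baseline_window_s <- default_baseline(tfr$label)
  inb <- tfr$times_s >= baseline_window_s[1] &
    tfr$times_s <= baseline_window_s[2]
  if (!any(inb)) stop("baseline window lies outside the TFR time axis")
  B <- rowMeans(tfr$power[, inb, drop = FALSE])
  zero <- which(B == 0)
  if (length(zero))
    stop("zero baseline power at frequency ",
         paste(tfr$freqs_hz[zero], collapse = ", "), " Hz")
  if (per_trial) {
    if (is.null(tfr$trials))
      stop("per-trial normalization needs compute_tfr(keep_trials = TRUE)")
    ntr <- dim(tfr$trials)[1]
    acc <- 0
    for (i in seq_len(ntr)) {
      Pi <- matrix(tfr$trials[i, , ], dim(tfr$trials)[2], dim(tfr$trials)[3])
      Bi <- rowMeans(Pi[, inb, drop = FALSE])
      if (any(Bi == 0)) stop("zero baseline power in trial ", i)
      acc <- acc + 100 * sweep(sweep(Pi, 1, Bi, "-"), 1, Bi, "/")
    }
    tfr$power <- acc / ntr
  } else {
    tfr$power <- 100 * sweep(sweep(tfr$power, 1, B, "-"), 1, B, "/")
  }
  tfr$normalized <- TRUE
  tfr$baseline_window_s <- baseline_window_s
  tfr
}

#' Average a TFR across a frequency band
#'
#' Arithmetic mean across the band's frequency bins at each time point (the
#' 60-200 Hz band time course).
#'
#' @param tfr a `tfr_map`.
#' @param band_hz `c(lo, hi)` band limits in Hz.
#' @return numeric time series (same time axis as the map).
#' @export
band_average <- function(tfr, band_hz = c(60, 200)) {
  stopifnot(inherits(tfr, "tfr_map"))
  inb <- tfr$freqs_hz >= band_hz[1] & tfr$freqs_hz <= band_hz[2]
  if (!any(inb)) stop("band lies outside the TFR frequency axis")
  colMeans(tfr$power[inb, , drop = FALSE])
}

#' Peak frequency of a TFR over an analysis window
#'
#' Averages the map over the requested time window per frequency and returns
#' the frequency of the maximum (ties resolve to the lowest frequency) with
#' its value -- the spectrum-inset readout of the time-frequency maps.
#'
#' @param tfr a `tfr_map` (typically baseline-normalized).
#' @param analysis_window_s `c(from, to)` seconds relative to onset; the
#'   default hugs the event support (as the spectrum insets average power
#'   "during the peak activity"): `[0, 0.25]` s for epileptic spikes,
#'   `[0, max(times)]` for the longer patterns.
#' @return list with `f_peak_hz` and `peak_value` (% change if normalized).
#' @export
peak_frequency <- function(tfr, analysis_window_s = NULL) {
  stopifnot(inherits(tfr, "tfr_map"))
  if (is.null(analysis_window_s))
    analysis_window_s <- c(0, if (tfr$label == "ES") 0.25 else max(tfr$times_s))
  inw <- tfr$times_s >= analysis_window_s[1] &
    tfr$times_s <= analysis_window_s[2]
  if (!any(inw)) stop("analysis window lies outside the TFR time axis")
  spec <- rowMeans(tfr$power[, inw, drop = FALSE])
  k <- which.max(spec)          # which.max returns the first (lowest) maximum
  list(f_peak_hz = tfr$freqs_hz[k], peak_value = spec[k], spectrum = spec)
}

#' Write a TFR map as TSV (+ JSON parameters)
#'
#' @param tfr a `tfr_map`.
#' @param prefix output path prefix; writes `<prefix>.tsv` (freq x time matrix
#'   with headers) and `<prefix>.json` (parameters).
#' @export
write_tfr <- function(tfr, prefix) {
  m <- as.data.frame(tfr$power)
  names(m) <- sprintf("t%.3f", tfr$times_s)
  m <- cbind(freq_hz = tfr$freqs_hz, m)
  utils::write.table(m, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(label = tfr$label, window_s = tfr$window_s, step_s = tfr$step_s,
         normalized = tfr$normalized,
         baseline_window_s = tfr$baseline_window_s),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
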