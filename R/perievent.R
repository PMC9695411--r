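#' Gaussian-kernel peri-event firing rate
#'
#' For every aligned event onset, evaluates the unit's instantaneous firing
#' rate on a 1 ms grid over the peri-event window as a sum of Gaussian kernels
#' centered on the spikes (`sigma_s` = 10 ms for epileptic spikes, 50 ms for
#' the longer patterns). Kernels are truncated at `+/- 4 sigma`; spikes near
#' epoch edges lose the truncated mass (no reflection), so the per-trial rate
#' integral equals the spike count only for spikes at least `3-4 sigma` from
#' the edges.
#'
#' @param train a [spike_train].
#' @param onsets_s aligned event onsets (s), e.g. `tm$onsets_s` after
#'   [align_trials].
#' @param window_s `c(pre, post)` peri-event window (s).
#' @param sigma_s Gaussian kernel SD (s, > 0).
#' @param fs_hz rate-grid resolution (default 1000 Hz).
#' @param label pattern label carried for downstream defaults.
#' @param unit_id identifier carried into reports.
#' @return An object of class `perievent_rate`: `rate` (trials x time,
#'   spikes/s), `times_s`, `onsets_s`, `sigma_s`, `label`, `unit_id`.
#' @export
kernel_rate <- function(train, onsets_s, window_s = c(-2, 2), sigma_s = 0.05,
                        fs_hz = 1000, label = NA_character_,
                        unit_id = train$unit_id) {
  stopifnot(inherits(train, "spike_train"), sigma_s > 0)
  tgrid <- seq(window_s[1], window_s[2], by = 1 / fs_hz)
  nt <- length(tgrid)
  ntr <- length(onsets_s)
  rate <- matrix(0, ntr, nt)
  halfw <- 4 * sigma_s
  for (i in seq_len(ntr)) {
    rel <- train$times_s - onsets_s[i]
    rel <- rel[rel >= window_s[1] - halfw & rel <= window_s[2] + halfw]
    for (s in rel) {
      j1 <- max(1L, ceiling((s - halfw - window_s[1]) * fs_hz) + 1L)
      j2 <- min(nt, floor((s + halfw - window_s[1]) * fs_hz) + 1L)
      if (j2 < j1) next
      jj <- j1:j2
      rate[i, jj] <- rate[i, jj] + stats::dnorm(tgrid[jj], s, sigma_s)
    }
  }
  structure(list(rate = rate, times_s = tgrid, onsets_s = onsets_s,
                 sigma_s = sigma_s, window_s = window_s, fs_hz = fs_hz,
                 label = label, unit_id = unit_id),
            class = "perievent_rate")
}

#' @export
print.perievent_rate <- function(x, ...) {
  cat(sprintf("<perievent_rate> unit %s%s: %d trials x %d samples, sigma %g ms\n",
              x$unit_id, if (is.na(x$label)) "" else paste0(" / ", x$label),
              nrow(x$rate), ncol(x$rate), 1000 * x$sigma_s))
  invisible(x)
}

#' Trial-average peri-event rate
#' @param per a `perievent_rate`.
#' @return numeric vector, spikes/s on the 1 ms grid.
#' @export
avg_rate <- function(per) colMeans(per$rate)

#' Bin peri-event rates into equal time bins
#'
#' Averages each trial's 1 ms rate samples within `n_bins` equal-width bins
#' spanning the peri-event window (the 100-bin trial rates used for the
#' cluster statistics).
#'
#' @param per a `perievent_rate`.
#' @param n_bins number of bins (default 100).
#' @return trials x `n_bins` matrix with attributes `bin_centers_s` and
#'   `bin_width_s`.
#' @export
bin_rates <- function(per, n_bins = 100) {
  stopifnot(inherits(per, "perievent_rate"))
  w <- per$window_s
  bw <- diff(w) / n_bins
  g <- pmin(n_bins, floor((per$times_s - w[1]) / bw) + 1L)
  binned <- t(rowsum(t(per$rate), g) / as.vector(table(g)))
  dimnames(binned) <- NULL
  attr(binned, "bin_centers_s") <- w[1] + (seq_len(n_bins) - 0.5) * bw
  attr(binned, "bin_width_s") <- bw
  binned
}

#' Correlation between average peri-event rate and average LFP
#'
#' Pearson correlation between a unit's trial-average time-locked firing rate
#' and the trial-average time-locked LFP of the same pattern, on a common
#' time axis. Inverse (suppressed) units yield negative coefficients.
#'
#' @param avg_rate_vec,avg_lfp_vec equal-length numeric vectors.
#' @return list with `rho` and `status` (`"ok"`, or `"zero-variance"` with
#'   `rho = NA`).
#' @export
rate_lfp_correlation <- function(avg_rate_vec, avg_lfp_vec) {
  if (length(avg_rate_vec) != length(avg_lfp_vec))
    stop("rate and LFP averages must share one time axis")
  if (stats::sd(avg_rate_vec) == 0 || stats::sd(avg_lfp_vec) == 0)
    return(list(rho = NA_real_, status = "zero-variance"))
  list(rho = stats::cor(avg_rate_vec, avg_lfp_vec), status = "ok")
}

#' Maximal significant rate modulation versus baseline
#'
#' Within the significant clusters found by [cluster_permutation_test],
#' expresses the unit's firing-rate excursion as a percentage of its baseline
#' rate: `up = 100 * (max significant-bin average rate - baseline) /
#' baseline` over up-clusters, and `down = 100 * (baseline - min
#' significant-bin average rate) / baseline` over down-clusters (100 =
#' complete silence). The baseline is the average binned rate over the
#' pre-event baseline-window bins by default; pass `baseline_fr` to use a
#' global resting rate instead. A direction without a significant cluster is
#' returned as `NA` with its significance flag `FALSE` (reported "n.s.",
#' never 0). `measure = "mean"` swaps the extreme bin for the cluster mean.
#'
#' @param binned trials x bins matrix from [bin_rates].
#' @param clusters a `cluster_result` from [cluster_permutation_test].
#' @param baseline_window_s `c(from, to)` s; default from the pattern label.
#' @param label pattern label (for the default baseline window).
#' @param baseline_fr optional externally supplied baseline rate (Hz).
#' @param measure `"peak"` (default) or `"mean"` cluster summary.
#' @return list with `up_pct`, `down_pct`, `up_sig`, `down_sig`,
#'   `baseline_fr`, `status`.
#' @export
modulation_percent <- function(binned, clusters, baseline_window_s = NULL,
                               label = "PD+F", baseline_fr = NULL,
                               measure = c("peak", "mean")) {
  measure <- match.arg(measure)
  centers <- attr(binned, "bin_centers_s")
  if (is.null(baseline_window_s)) baseline_window_s <- default_baseline(label)
  avg <- colMeans(binned)
  if (is.null(baseline_fr)) {
    inb <- centers >= baseline_window_s[1] & centers <= baseline_window_s[2]
    if (!any(inb)) stop("baseline window covers no bins")
    baseline_fr <- mean(avg[inb])
  }
  if (baseline_fr == 0)
    return(list(up_pct = NA_real_, down_pct = NA_real_, up_sig = FALSE,
                down_sig = FALSE, baseline_fr = 0, status = "zero-baseline"))
  cl <- clusters$clusters
  sig <- cl[cl$significant, , drop = FALSE]
  pick <- function(dir, f) {
    rows <- sig[sig$direction == dir, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    bins <- unlist(lapply(seq_len(nrow(rows)), function(i)
      rows$start_bin[i]:rows$end_bin[i]))
    if (measure == "peak") f(avg[bins]) else mean(avg[bins])
  }
  up_v <- pick("up", max)
  down_v <- pick("down", min)
  list(
    up_pct = if (is.null(up_v)) NA_real_ else
      100 * (up_v - baseline_fr) / baseline_fr,
    down_pct = if (is.null(down_v)) NA_real_ else
      100 * (baseline_fr - down_v) / baseline_fr,
    up_sig = !is.null(up_v), down_sig = !is.null(down_v),
    baseline_fr = baseline_fr, status = "ok")
}

#' Seizure-locked spike raster
#'
#' Re-references every unit's spike times to each annotated seizure onset.
#' Purely descriptive: with a handful of seizures no inferential statistics
#' are attached -- the summary reports pre-/post-onset mean rates per unit.
#'
#' @param trains list of [spike_train].
#' @param seizure_onsets_s onset times (s), at least one.
#' @param window_s `c(pre, post)` raster window (s) around onset.
#' @return list of class `seizure_raster`: `raster` (per unit, a list of
#'   per-seizure relative spike-time vectors), `summary` (data.frame:
#'   `unit_id`, `pre_rate_hz`, `post_rate_hz`, `ratio`), `window_s`.
#' @export
seizure_raster <- function(trains, seizure_onsets_s, window_s = c(-30, 60)) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  if (length(seizure_onsets_s) < 1) stop("at least one seizure onset required")
  raster <- lapply(trains, function(tr)
    lapply(seizure_onsets_s, function(on) {
      rel <- tr$times_s - on
      rel[rel >= window_s[1] & rel <= window_s[2]]
    }))
  names(raster) <- vapply(trains, `[[`, "", "unit_id")
  summ <- do.call(rbind, lapply(seq_along(trains), function(i) {
    rel <- unlist(raster[[i]])
    n_sz <- length(seizure_onsets_s)
    pre <- sum(rel < 0) / (abs(window_s[1]) * n_sz)
    post <- sum(rel >= 0) / (window_s[2] * n_sz)
    data.frame(unit_id = trains[[i]]$unit_id, pre_rate_hz = pre,
               post_rate_hz = post,
               ratio = if (pre > 0) post / pre else NA_real_)
  }))
  structure(list(raster = raster, summary = summ, window_s = window_s,
                 n_seizures = length(seizure_onsets_s)),
            class = "seizure_raster")
}

#' @export
print.seizure_raster <- function(x, ...) {
  cat(sprintf("<seizure_raster> %d units x %d seizures, window [%g, %g] s\n",
              length(x$raster), x$n_seizures, x$window_s[1], x$window_s[2]))
  print(x$summary)
  invisible(x)
}
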