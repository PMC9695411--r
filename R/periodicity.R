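#' Periodicity of a deflection train
#'
#' For a train of deflection times, computes the inter-deflection intervals,
#' their mean period, and the fraction of intervals deviating strictly less
#' than 25% from the mean period -- the criterion under which a train with at
#' least three consecutive slow waves counts as periodic. The deviation
#' denominator is the number of intervals (`n - 1`) by default; set
#' `denominator = "deflections"` to divide by the number of deflections
#' instead (both readings of a "conforming deflections" count are possible).
#'
#' @param deflection_times_s sorted, strictly increasing times (s).
#' @param tolerance_frac deviation tolerance as a fraction of the mean period
#'   (default 0.25, strict inequality).
#' @param denominator `"intervals"` (default) or `"deflections"`.
#' @return list of class `periodicity_report`: `n_deflections`,
#'   `mean_period_s`, `n_conforming`, `frac_within_25`, `pct` (nearest-integer
#'   percentage), `periodic` (>= 3 deflections), `dispersion` (interval SD).
#' @export
periodicity_fraction <- function(deflection_times_s, tolerance_frac = 0.25,
                                 denominator = c("intervals", "deflections")) {
  denominator <- match.arg(denominator)
  t <- as.numeric(deflection_times_s)
  if (length(t) < 2) stop("periodicity undefined for fewer than 2 deflections")
  if (is.unsorted(t, strictly = TRUE))
    stop("deflection times must be sorted and strictly increasing")
  ivl <- diff(t)
  mp <- mean(ivl)
  # |ivl - mean|/mean < tol evaluated as |k*ivl - S| < tol*S (k intervals of
  # total S) so exact-boundary cases are not decided by division round-off
  k <- length(ivl); S <- sum(ivl)
  conforming <- sum(abs(k * ivl - S) < tolerance_frac * S)
  denom <- if (denominator == "intervals") length(ivl) else length(t)
  frac <- conforming / denom
  structure(list(n_deflections = length(t), mean_period_s = mp,
                 n_conforming = conforming, frac_within_25 = frac,
                 pct = periodicity_percent(conforming, denom),
                 periodic = length(t) >= 3,
                 dispersion = stats::sd(ivl)),
            class = "periodicity_report")
}

#' Conforming-count percentage, rounded to the nearest integer
#'
#' The summary-table arithmetic: `round(100 * conforming / total)`, e.g.
#' 124/150 -> 83.
#'
#' @param conforming,total non-negative counts, `total > 0`.
#' @return integer percentage.
#' @export
periodicity_percent <- function(conforming, total) {
  stopifnot(all(total > 0), all(conforming >= 0), all(conforming <= total))
  as.integer(round(100 * conforming / total))
}

#' @export
print.periodicity_report <- function(x, ...) {
  cat(sprintf("<periodicity> %d deflections, mean period %.3f s, %d%% within 25%% (%s)\n",
              x$n_deflections, x$mean_period_s, x$pct,
              if (x$periodic) "periodic" else "not periodic: < 3 deflections"))
  invisible(x)
}

#' Modal inter-event interval
#'
#' Histograms the inter-onset intervals of one pattern with a fixed bin width
#' and returns the center of the modal bin -- the most frequent time interval
#' between events. Ties between equally full bins resolve to the smallest
#' interval. Unit-agnostic (seconds in, seconds out).
#'
#' @param event_onsets_s sorted onset times (s), at least 2.
#' @param bin_width_s histogram bin width (s, > 0; default 1).
#' @return list of class `interval_stats`: `n_events`, `lambda_mode_s`,
#'   `bin_width_s`, `intervals_s`.
#' @export
interval_mode <- function(event_onsets_s, bin_width_s = 1) {
  t <- as.numeric(event_onsets_s)
  if (length(t) < 2) stop("interval mode undefined for fewer than 2 events")
  if (bin_width_s <= 0) stop("bin_width_s must be > 0")
  ivl <- diff(sort(t))
  edges <- seq(0, (floor(max(ivl) / bin_width_s) + 1) * bin_width_s,
               by = bin_width_s)
  counts <- graphics::hist(ivl, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  k <- which.max(counts)  # first maximum = smallest interval on ties
  structure(list(n_events = length(t),
                 lambda_mode_s = edges[k] + bin_width_s / 2,
                 bin_width_s = bin_width_s, intervals_s = ivl),
            class = "interval_stats")
}

#' Per-pattern descriptive summary table
#'
#' One row per pattern label present in the annotations: hours analyzed,
#' event count, modal inter-event interval, and (when ground-truth deflection
#' times are supplied, e.g. for periodic trains) the mean intra-train period
#' and periodicity percentage pooled across trains.
#'
#' @param annotations an [annotation_table].
#' @param duration_s recording length (s).
#' @param deflection_times per-label list of per-train deflection-time
#'   vectors, or `NULL`.
#' @param bin_width_s passed to [interval_mode].
#' @return data.frame with columns `label`, `t_h`, `n`, `lambda_mode_s`,
#'   `mean_period_s`, `periodicity_pct`.
#' @export
pattern_summary <- function(annotations, duration_s, deflection_times = NULL,
                            bin_width_s = 1) {
  labs <- intersect(IP_PATTERN_LABELS, unique(annotations$label))
  rows <- lapply(labs, function(lab) {
    ev <- annotations_with_label(annotations, lab)
    lam <- if (nrow(ev) >= 2)
      interval_mode(ev$start_s, bin_width_s)$lambda_mode_s else NA_real_
    mp <- pct <- NA_real_
    dt <- deflection_times[[lab]]
    if (!is.null(dt)) {
      reps <- lapply(dt[vapply(dt, length, 0L) >= 3], periodicity_fraction)
      if (length(reps)) {
        mp <- mean(vapply(reps, `[[`, 0, "mean_period_s"))
        conf <- sum(vapply(reps, `[[`, 0, "n_conforming"))
        tot <- sum(vapply(reps, function(r) r$n_deflections - 1L, 0L))
        pct <- periodicity_percent(conf, tot)
      }
    }
    data.frame(label = lab, t_h = duration_s / 3600, n = nrow(ev),
               lambda_mode_s = lam, mean_period_s = mp,
               periodicity_pct = pct)
  })
  do.call(rbind, rows)
}
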