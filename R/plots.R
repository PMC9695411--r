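#' Plot a time-frequency map
#'
#' Base-graphics image of a `tfr_map` (time x frequency, color = power or %
#' change) with an optional spectrum inset readout via [peak_frequency].
#'
#' @param x a `tfr_map`.
#' @param main title.
#' @param ... passed to [graphics::image].
#' @export
plot.tfr_map <- function(x, main = x$label, ...) {
  graphics::image(x$times_s, x$freqs_hz, t(x$power),
                  xlab = "time from onset (s)", ylab = "frequency (Hz)",
                  main = main, useRaster = TRUE, ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Peri-event raster with PSTH
#'
#' Trial-average rate trace above a spike raster, both time-locked to the
#' aligned event onsets.
#'
#' @param per a `perievent_rate`.
#' @param train the [spike_train] the rates came from.
#' @param main title.
#' @export
plot_psth_raster <- function(per, train, main = per$unit_id) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(per$times_s, avg_rate(per), type = "l",
                 xlab = "", ylab = "rate (spikes/s)", main = main)
  graphics::abline(v = 0, lty = 2)
  graphics::plot(NULL, xlim = per$window_s, ylim = c(0, length(per$onsets_s)),
                 xlab = "time from onset (s)", ylab = "trial")
  for (i in seq_along(per$onsets_s)) {
    rel <- train$times_s - per$onsets_s[i]
    rel <- rel[rel >= per$window_s[1] & rel <= per$window_s[2]]
    if (length(rel))
      graphics::segments(rel, i - 0.9, rel, i - 0.1)
  }
  graphics::abline(v = 0, lty = 2)
  invisible(per)
}

#' Seizure-locked raster plot
#'
#' @param x a `seizure_raster`.
#' @param ... unused.
#' @export
plot.seizure_raster <- function(x, ...) {
  rows <- unlist(lapply(x$raster, length))
  graphics::plot(NULL, xlim = x$window_s, ylim = c(0, sum(rows)),
                 xlab = "time from seizure onset (s)", ylab = "seizure x unit")
  y <- 0
  for (u in seq_along(x$raster)) {
    for (s in x$raster[[u]]) {
      if (length(s)) graphics::segments(s, y + 0.1, s, y + 0.9,
                                        col = grDevices::grey(0.2 + 0.6 *
                                                                (u - 1) /
                                                                max(1, length(x$raster) - 1)))
      y <- y + 1
    }
  }
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
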