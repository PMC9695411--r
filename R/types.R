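#' Closed vocabulary of annotation labels
#'
#' Pattern labels used throughout the pipeline: the three interictal pattern
#' (IP) classes (periodic discharges plus fast activity, sporadic discharges
#' plus fast activity, epileptic spikes), periodic fast activity (PF, the
#' slow-wave-free variant), seizures, and artifact periods.
#'
#' @export
IP_LABELS <- c("PD+F", "SD+F", "ES", "PF", "seizure", "artifact")

#' Labels counted as interictal patterns (used for baseline-window exclusion)
#' @export
IP_PATTERN_LABELS <- c("PD+F", "SD+F", "ES", "PF")

#' Construct a sampled LFP signal
#'
#' One channel of continuous local field potential, amplitudes in microvolts.
#' Sample `i` (1-based) occurs at `t0_s + (i - 1) / fs_hz`.
#'
#' @param samples numeric vector of amplitudes (uV); must be finite.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param channel_id channel name.
#' @param t0_s time of the first sample in seconds.
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(samples, fs_hz, channel_id = "u1", t0_s = 0) {
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0)
    stop("fs_hz must be a positive finite scalar")
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("samples must be finite")
  structure(
    list(samples = samples, fs_hz = fs_hz,
         channel_id = as.character(channel_id), t0_s = as.numeric(t0_s)),
    class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> channel %s: %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              x$channel_id, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz, x$t0_s))
  invisible(x)
}

#' Duration of a sampled signal in seconds
#' @param x a `sampled_signal`.
#' @export
signal_duration <- function(x) length(x$samples) / x$fs_hz

#' Construct an annotation table
#'
#' Labeled events (interictal patterns, seizures, artifact periods) with
#' half-open time support `[start_s, end_s)` on a named channel. Rows are
#' sorted by onset. Labels must come from [IP_LABELS].
#'
#' @param label character vector of labels.
#' @param channel_id character vector (recycled) of channel names.
#' @param start_s,end_s numeric onset/offset in seconds from recording start.
#' @return A `data.frame` with class `annotation_table`.
#' @export
annotation_table <- function(label = character(), channel_id = character(0),
                             start_s = numeric(), end_s = numeric()) {
  n <- length(label)
  if (n > 0 && length(channel_id) == 1L) channel_id <- rep(channel_id, n)
  if (n == 0 && length(channel_id) == 0L) channel_id <- character()
  df <- data.frame(label = as.character(label),
                   channel = as.character(channel_id),
                   start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   stringsAsFactors = FALSE)
  validate_annotations(df)
}

validate_annotations <- function(df) {
  req <- c("label", "channel", "start_s", "end_s")
  if (!all(req %in% names(df)))
    stop("annotation table requires columns: ", paste(req, collapse = ", "))
  bad <- which(!(df$label %in% IP_LABELS))
  if (length(bad))
    stop(sprintf("unknown annotation label(s) %s in row(s) %s; allowed: %s",
                 paste(unique(df$label[bad]), collapse = ", "),
                 paste(bad, collapse = ", "),
                 paste(IP_LABELS, collapse = ", ")))
  bad <- which(df$end_s < df$start_s)
  if (length(bad))
    stop("end_s < start_s in annotation row(s): ", paste(bad, collapse = ", "))
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Construct a spike train
#'
#' Sorted spike times of one unit with optional quality metrics.
#'
#' @param times_s numeric vector of spike times (seconds); strictly increasing.
#' @param unit_id unit identifier.
#' @param amplitude_uV mean absolute trough amplitude (uV), optional.
#' @param unit_class `"SUA"`, `"MUA"` or `NA`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times_s, unit_id = "u1", amplitude_uV = NA_real_,
                        unit_class = NA_character_) {
  times_s <- as.numeric(times_s)
  if (is.unsorted(times_s, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (!is.na(unit_class) && !unit_class %in% c("SUA", "MUA"))
    stop("unit_class must be SUA, MUA or NA")
  structure(list(unit_id = as.character(unit_id), times_s = times_s,
                 amplitude_uV = amplitude_uV, unit_class = unit_class),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes%s\n", x$unit_id,
              length(x$times_s),
              if (!is.na(x$unit_class)) paste0(" (", x$unit_class, ")") else ""))
  invisible(x)
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. seed = NULL leaves the
# global stream untouched (draws advance it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Do intervals [a1, a2) and [b1, b2) overlap?
intervals_overlap <- function(a1, a2, b1, b2) a1 < b2 & b1 < a2

# Rows of an annotation table with a given label (or any of several)
annotations_with_label <- function(ann, labels) {
  ann[ann$label %in% labels, , drop = FALSE]
}
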