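#' Per-nodule synthesis presets
#'
#' Parameters of the surrogate-recording generator for the four heterotopic
#' nodules. The narrow-band fast-activity frequencies superimposed on each
#' interictal pattern, the intra-train deflection period and its jitter, and
#' the slow-wave durations are taken from the recorded values for each nodule;
#' the inter-event interval modes come from the per-pattern descriptive
#' statistics. Nodule 3 expresses periodic fast activity without slow waves
#' (PF) and has no sporadic-discharge (SD+F) pattern, so `sdf_fast_hz` is `NA`
#' there. The mapping of SD+F frequencies 96/111/77 Hz onto nodules 1/2/4 is
#' configurable (`sdf_fast_hz` argument) because published accounts of which
#' nodules express SD+F are not fully consistent.
#'
#' @param nodule_id integer 1-4.
#' @param sdf_fast_hz override for the SD+F fast-activity frequency (Hz).
#' @return A list of class `nodule_preset`.
#' @export
nodule_preset <- function(nodule_id, sdf_fast_hz = NULL) {
  if (!nodule_id %in% 1:4) stop("nodule_id must be 1, 2, 3 or 4")
  tab <- list(
    list(pdf_fast_hz = 92,  es_fast_hz = 102, sdf_fast_hz = 96,
         pdf_period_s = 0.511, pdf_jitter_frac = 0.187,
         sdf_slow_dur_s = 0.75, sdf_burst_dur_s = 0.5,
         event_mode_s = c("PD+F" = 6, "SD+F" = 4, "ES" = 0.59)),
    list(pdf_fast_hz = 135, es_fast_hz = 134, sdf_fast_hz = 111,
         pdf_period_s = 0.574, pdf_jitter_frac = 0.206,
         sdf_slow_dur_s = 3.0, sdf_burst_dur_s = 1.0,
         event_mode_s = c("PD+F" = 6, "SD+F" = 6, "ES" = 0.49)),
    list(pdf_fast_hz = 106, es_fast_hz = 121, sdf_fast_hz = NA_real_,
         pdf_period_s = 1.074, pdf_jitter_frac = 0.176,
         sdf_slow_dur_s = NA_real_, sdf_burst_dur_s = NA_real_,
         event_mode_s = c("PD+F" = 8, "ES" = 0.37)),
    list(pdf_fast_hz = 81,  es_fast_hz = 97,  sdf_fast_hz = 77,
         pdf_period_s = 1.723, pdf_jitter_frac = 0.196,
         sdf_slow_dur_s = 2.0, sdf_burst_dur_s = 1.5,
         event_mode_s = c("PD+F" = 12, "SD+F" = 5, "ES" = 0.36))
  )
  p <- tab[[nodule_id]]
  if (!is.null(sdf_fast_hz)) p$sdf_fast_hz <- sdf_fast_hz
  p$nodule_id <- as.integer(nodule_id)
  freqs <- c(p$pdf_fast_hz, p$es_fast_hz, p$sdf_fast_hz)
  stopifnot(all(is.na(freqs) | (freqs >= 60 & freqs <= 200)),
            p$pdf_jitter_frac >= 0)
  class(p) <- "nodule_preset"
  p
}

#' Generate 1/f background LFP
#'
#' Colored Gaussian noise with power spectral density proportional to
#' `1/f^pink_exponent`, scaled to a requested RMS amplitude. Emulates the
#' low-amplitude background activity of heterotopic gray matter between
#' epileptiform events. Synthesized in the Fourier domain (DC removed).
#'
#' @param duration_s duration in seconds (> 0).
#' @param fs_hz sampling rate in Hz (>= 1000).
#' @param pink_exponent spectral exponent in `[0, 2]` (0 = white, 1 = pink).
#' @param rms_uV target root-mean-square amplitude in uV.
#' @param seed integer seed for reproducibility, or `NULL`.
#' @param channel_id channel name.
#' @return A [sampled_signal].
#' @export
generate_background <- function(duration_s, fs_hz, pink_exponent = 1,
                                rms_uV = 10, seed = NULL, channel_id = "u1") {
  if (!is.finite(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  if (!is.finite(fs_hz) || fs_hz < 1000) stop("fs_hz must be >= 1000")
  if (pink_exponent < 0 || pink_exponent > 2)
    stop("pink_exponent must lie in [0, 2]")
  n <- round(duration_s * fs_hz)
  x <- with_seed(seed, {
    w <- stats::rnorm(n)
    if (pink_exponent == 0) {
      w
    } else {
      X <- stats::fft(w)
      k <- 0:(n - 1)
      fidx <- pmin(k, n - k)            # symmetric frequency index
      amp <- c(0, fidx[-1]^(-pink_exponent / 2))
      Re(stats::fft(X * amp, inverse = TRUE)) / n
    }
  })
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (rms_uV / s)
  sampled_signal(x, fs_hz, channel_id = channel_id)
}

# Raised-cosine lobe of given duration (s) and signed amplitude, sampled at fs.
raised_cosine <- function(dur_s, amp_uV, fs_hz) {
  n <- max(2L, round(dur_s * fs_hz))
  t <- seq_len(n) - 1
  amp_uV * 0.5 * (1 - cos(2 * pi * t / (n - 1)))
}

# Hanning-windowed sinusoidal burst: narrow-band fast activity.
fast_burst <- function(freq_hz, dur_s, amp_uV, fs_hz, phase = 0) {
  n <- max(2L, round(dur_s * fs_hz))
  t <- (seq_len(n) - 1) / fs_hz
  env <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  amp_uV * env * sin(2 * pi * freq_hz * t + phase)
}

add_at <- function(x, seg, i0) {
  # add segment into x starting at sample index i0 (1-based), clipping to x
  i1 <- max(1L, i0); i2 <- min(length(x), i0 + length(seg) - 1L)
  if (i2 < i1) return(x)
  x[i1:i2] <- x[i1:i2] + seg[(i1 - i0 + 1L):(i2 - i0 + 1L)]
  x
}

#' Render one interictal-pattern event
#'
#' Deterministically (given a seed) renders the waveform of a single event of
#' one of the three interictal pattern classes:
#' \describe{
#'   \item{PD+F / PF}{`n_deflections >= 3` negative raised-cosine slow waves at
#'     period `pdf_period_s` with multiplicative period jitter
#'     `pdf_jitter_frac`, each deflection carrying a Hanning-enveloped
#'     oscillatory burst at `pdf_fast_hz`.}
#'   \item{SD+F}{one slow wave of duration `sdf_slow_dur_s` with a superimposed
#'     burst at `sdf_fast_hz` lasting `sdf_burst_dur_s`.}
#'   \item{ES}{a sharp difference-of-Gaussians transient (~60-80 ms) with a
#'     ~100 ms burst at `es_fast_hz`.}
#' }
#'
#' @param kind `"PD+F"`, `"SD+F"` or `"ES"` (PF renders as PD+F without slow
#'   lobes).
#' @param preset a [nodule_preset].
#' @param fs_hz sampling rate of the rendered segment.
#' @param seed seed for the period jitter and burst phase, or `NULL`.
#' @param n_deflections number of slow waves for PD+F (>= 3).
#' @param slow_amp_uV,burst_amp_uV component amplitudes.
#' @return list with `samples`, `fs_hz`, `duration_s`, and
#'   `deflection_times_s` (ground-truth deflection times relative to segment
#'   start).
#' @export
render_ip_event <- function(kind, preset, fs_hz = 1000, seed = NULL,
                            n_deflections = 5, slow_amp_uV = 150,
                            burst_amp_uV = 30) {
  stopifnot(inherits(preset, "nodule_preset"))
  if (!kind %in% c("PD+F", "SD+F", "ES", "PF"))
    stop("kind must be one of PD+F, SD+F, ES, PF")
  with_seed(seed, {
    if (kind %in% c("PD+F", "PF")) {
      if (n_deflections < 3)
        stop("periodic patterns require at least three deflections")
      per <- preset$pdf_period_s
      ivl <- per * pmax(0.3, 1 + preset$pdf_jitter_frac *
                          stats::rnorm(n_deflections - 1))
      defl <- c(0, cumsum(ivl))
      lobe_dur <- min(0.3, 0.6 * per)
      dur <- defl[n_deflections] + max(lobe_dur, 0.2)
      x <- numeric(round(dur * fs_hz))
      for (d in defl) {
        i0 <- round(d * fs_hz) + 1L
        if (kind == "PD+F")
          x <- add_at(x, raised_cosine(lobe_dur, slow_amp_uV, fs_hz), i0)
        x <- add_at(x, fast_burst(preset$pdf_fast_hz, 0.15, burst_amp_uV,
                                  fs_hz, phase = stats::runif(1, 0, 2 * pi)), i0)
      }
      list(samples = x, fs_hz = fs_hz, duration_s = length(x) / fs_hz,
           deflection_times_s = defl)
    } else if (kind == "SD+F") {
      if (is.na(preset$sdf_fast_hz))
        stop(sprintf("nodule %d preset has no SD+F pattern", preset$nodule_id))
      dur <- preset$sdf_slow_dur_s
      x <- numeric(round((dur + 0.1) * fs_hz))
      x <- add_at(x, raised_cosine(dur, 1.3 * slow_amp_uV, fs_hz), 1L)
      x <- add_at(x, fast_burst(preset$sdf_fast_hz, preset$sdf_burst_dur_s,
                                burst_amp_uV, fs_hz,
                                phase = stats::runif(1, 0, 2 * pi)),
                  round(0.05 * fs_hz) + 1L)
      list(samples = x, fs_hz = fs_hz, duration_s = length(x) / fs_hz,
           deflection_times_s = dur / 2)
    } else { # ES
      n <- round(0.35 * fs_hz)
      t <- (seq_len(n) - 1) / fs_hz
      t0 <- 0.06
      sharp <- 1.6 * slow_amp_uV * (exp(-(t - t0)^2 / (2 * 0.010^2)) -
                                      0.25 * exp(-(t - t0)^2 / (2 * 0.030^2)))
      x <- sharp + add_at(numeric(n),
                          fast_burst(preset$es_fast_hz, 0.1, burst_amp_uV,
                                     fs_hz,
                                     phase = stats::runif(1, 0, 2 * pi)),
                          round((t0 - 0.05) * fs_hz) + 1L)
      # after-going slow wave, as in the recorded spike-and-slow-wave forms
      x <- add_at(x, raised_cosine(0.25, 0.5 * slow_amp_uV, fs_hz),
                  round(t0 * fs_hz) + 1L)
      list(samples = x, fs_hz = fs_hz, duration_s = n / fs_hz,
           deflection_times_s = t0)
    }
  })
}

#' Generate a series of interictal-pattern events over background LFP
#'
#' Inserts rendered events of each requested kind into 1/f background noise.
#' Inter-onset intervals are drawn per kind from a log-normal distribution
#' parameterized by its mode (the most frequent interval, mimicking the
#' heavy-tailed mode-vs-mean discrepancy of the recorded inter-event
#' statistics); an interval shorter than the previous event's duration is
#' redrawn so events of the same kind never overlap.
#'
#' @param preset a [nodule_preset].
#' @param duration_s recording length in seconds.
#' @param fs_hz sampling rate (>= 1000).
#' @param modes_s named numeric vector of inter-onset interval modes per kind
#'   (seconds); a kind absent or with value 0/NA generates no events. Default:
#'   the preset's `event_mode_s`.
#' @param sigma_log log-scale SD of the log-normal interval distribution.
#' @param background list of arguments passed to [generate_background].
#' @param n_deflections deflections per PD+F train.
#' @param seed integer seed; the full series is reproducible from it.
#' @param channel_id channel name.
#' @param max_retries bounded redraws per placement before failing.
#' @return list with `signal` ([sampled_signal]), `annotations`
#'   ([annotation_table]), and `events` (per-event ground truth: kind, onset,
#'   absolute deflection times).
#' @export
generate_ip_series <- function(preset, duration_s, fs_hz = 1000,
                               modes_s = NULL, sigma_log = 0.5,
                               background = list(pink_exponent = 1, rms_uV = 10),
                               n_deflections = 5, seed = NULL,
                               channel_id = "u1", max_retries = 100) {
  stopifnot(inherits(preset, "nodule_preset"))
  if (is.null(modes_s)) modes_s <- preset$event_mode_s
  if (any(!is.na(modes_s) & modes_s < 0)) stop("interval modes must be >= 0")
  with_seed(seed, {
    bg <- do.call(generate_background,
                  c(list(duration_s = duration_s, fs_hz = fs_hz,
                         channel_id = channel_id), background))
    x <- bg$samples
    # log-normal with mode m: mode = exp(mu - sigma^2) => mu = log(m) + sigma^2
    draw_ivl <- function(m) stats::rlnorm(1, log(m) + sigma_log^2, sigma_log)
    events <- list()
    for (kind in names(modes_s)) {
      m <- modes_s[[kind]]
      if (is.na(m) || m <= 0) next
      t <- draw_ivl(m)
      prev_end <- -Inf
      while (TRUE) {
        ev <- render_ip_event(kind, preset, fs_hz = fs_hz,
                              n_deflections = n_deflections)
        if (t + ev$duration_s >= duration_s) break
        x <- add_at(x, ev$samples, round(t * fs_hz) + 1L)
        events[[length(events) + 1L]] <-
          list(kind = kind, onset_s = t, end_s = t + ev$duration_s,
               deflection_times_s = t + ev$deflection_times_s)
        prev_end <- t + ev$duration_s
        tries <- 0
        repeat {
          ivl <- draw_ivl(m)
          if (t + ivl >= prev_end) break
          tries <- tries + 1
          if (tries > max_retries)
            stop(sprintf("cannot place non-overlapping %s events at mode %g s",
                         kind, m))
        }
        t <- t + ivl
      }
    }
    ann <- if (length(events)) {
      annotation_table(
        label = vapply(events, `[[`, "", "kind"),
        channel_id = channel_id,
        start_s = vapply(events, `[[`, 0, "onset_s"),
        end_s = vapply(events, `[[`, 0, "end_s"))
    } else annotation_table()
    ord <- order(vapply(events, `[[`, 0, "onset_s"))
    list(signal = sampled_signal(x, fs_hz, channel_id = channel_id),
         annotations = ann, events = events[ord])
  })
}

#' Gain-profile archetypes for synthetic units
#'
#' Multiplicative firing-gain curves `g(t)` on a time axis relative to event
#' onset, mirroring the behaviors observed in the recorded units: a brief
#' phasic increase (epileptic-spike-locked), a sustained increase spanning the
#' slow wave, a periodic modulation following the deflections of a periodic
#' train, and an inverse (suppressed) profile with `g < 1` during the event.
#' Every archetype returns 1 outside its support; gains are >= 0 everywhere.
#'
#' @param peak peak gain (phasic/sustained/periodic) -- must be >= 0.
#' @param center_s,sigma_s Gaussian bump location/width (phasic).
#' @param onset_s,duration_s plateau support (sustained).
#' @param period_s,n_cycles,width_s periodic-modulation geometry.
#' @param floor_gain,window_s minimum gain and suppression window (inverse).
#' @return A function `g(t_rel, event_dur_s)` vectorized in `t_rel`.
#' @name gain_profiles
NULL

#' @rdname gain_profiles
#' @export
gain_phasic <- function(peak = 20, center_s = 0.06, sigma_s = 0.03) {
  stopifnot(peak >= 0)
  function(t, dur = NA) 1 + (peak - 1) * exp(-(t - center_s)^2 / (2 * sigma_s^2))
}

#' @rdname gain_profiles
#' @export
gain_sustained <- function(peak = 100, onset_s = 0, duration_s = 1) {
  stopifnot(peak >= 0)
  function(t, dur = NA) ifelse(t >= onset_s & t < onset_s + duration_s, peak, 1)
}

#' @rdname gain_profiles
#' @export
gain_periodic <- function(peak = 5, period_s = 0.5, n_cycles = 5,
                          width_s = 0.1) {
  stopifnot(peak >= 0)
  function(t, dur = NA) {
    g <- rep(1, length(t))
    for (k in seq_len(n_cycles) - 1) {
      c_k <- k * period_s + width_s
      g <- g + (peak - 1) * exp(-(t - c_k)^2 / (2 * (width_s / 2)^2))
    }
    g
  }
}

#' @rdname gain_profiles
#' @export
gain_inverse <- function(floor_gain = 0, window_s = c(-0.25, 0.25)) {
  stopifnot(floor_gain >= 0, floor_gain <= 1)
  function(t, dur = NA) ifelse(t >= window_s[1] & t < window_s[2], floor_gain, 1)
}

#' @rdname gain_profiles
#' @export
gain_ictal <- function(peak = 3) {
  stopifnot(peak >= 0)
  function(t, dur) ifelse(t >= 0 & t < dur, peak, 1)
}

#' Construct a unit gain profile
#'
#' Binds a baseline firing rate to per-pattern gain curves. During the
#' recording, the unit's instantaneous rate is
#' `lambda(t) = baseline_rate_hz * prod_k g_k(t - onset_k)` over all annotated
#' events `k` whose label has a gain curve.
#'
#' @param unit_id identifier.
#' @param baseline_rate_hz homogeneous baseline rate (> 0).
#' @param gains named list mapping annotation labels to gain functions (see
#'   [gain_profiles]).
#' @param inverse logical: unit is suppressed (all gains <= 1) during IPs.
#' @return list of class `unit_gain_profile`.
#' @export
unit_gain_profile <- function(unit_id, baseline_rate_hz, gains,
                              inverse = FALSE) {
  stopifnot(baseline_rate_hz > 0, is.list(gains))
  structure(list(unit_id = as.character(unit_id),
                 baseline_rate_hz = baseline_rate_hz,
                 gains = gains, inverse = inverse),
            class = "unit_gain_profile")
}

#' Instantaneous rate of a synthetic unit on a time grid
#'
#' @param profile a [unit_gain_profile].
#' @param annotations an [annotation_table].
#' @param duration_s recording length.
#' @param fs_grid_hz rate-grid resolution (default 1000 Hz).
#' @param pad_s how far before onset / after offset gain curves are evaluated.
#' @return numeric vector of `lambda(t)` (Hz) on the grid.
#' @export
unit_rate_on_grid <- function(profile, annotations, duration_s,
                              fs_grid_hz = 1000, pad_s = 2) {
  ng <- round(duration_s * fs_grid_hz)
  lam <- rep(profile$baseline_rate_hz, ng)
  for (i in seq_len(nrow(annotations))) {
    lab <- annotations$label[i]
    fn <- profile$gains[[lab]]
    if (is.null(fn)) next
    on <- annotations$start_s[i]
    dur <- annotations$end_s[i] - on
    i1 <- max(1L, floor((on - pad_s) * fs_grid_hz) + 1L)
    i2 <- min(ng, ceiling((on + dur + pad_s) * fs_grid_hz))
    if (i2 < i1) next
    tt <- (i1:i2 - 0.5) / fs_grid_hz - on
    g <- fn(tt, dur)
    if (any(g < 0)) stop("gain curves must be non-negative")
    lam[i1:i2] <- lam[i1:i2] * g
  }
  lam
}

#' Generate an event-modulated Poisson spike train
#'
#' Samples an inhomogeneous Poisson process by thinning: candidate spikes are
#' drawn homogeneously at the peak rate and accepted with probability
#' `lambda(t)/lambda_max`, where `lambda(t)` multiplies the unit's baseline
#' rate by the gain curve of every overlapping annotated event.
#'
#' @param annotations an [annotation_table] (ground truth event times).
#' @param profile a [unit_gain_profile].
#' @param duration_s recording length in seconds.
#' @param seed integer seed or `NULL`.
#' @param fs_grid_hz resolution of the rate grid used for thinning.
#' @param chunk_s chunk length for local-ceiling thinning (bounds candidate
#'   counts when gains of overlapping events stack multiplicatively).
#' @return A [spike_train]; times strictly increasing within `[0, duration_s]`.
#' @export
generate_unit_spikes <- function(annotations, profile, duration_s,
                                 seed = NULL, fs_grid_hz = 1000,
                                 chunk_s = 10) {
  stopifnot(inherits(profile, "unit_gain_profile"), duration_s > 0)
  lam <- unit_rate_on_grid(profile, annotations, duration_s, fs_grid_hz)
  ng <- length(lam)
  with_seed(seed, {
    # thin chunk-wise against the local rate ceiling: equivalent to global
    # thinning but bounded in candidates when gains stack multiplicatively
    ts <- list()
    nchunk <- ceiling(duration_s / chunk_s)
    for (c_i in seq_len(nchunk)) {
      t0 <- (c_i - 1) * chunk_s
      t1 <- min(duration_s, c_i * chunk_s)
      i0 <- floor(t0 * fs_grid_hz) + 1L
      i1 <- min(ng, ceiling(t1 * fs_grid_hz))
      lmax <- max(lam[i0:i1])
      if (lmax <= 0) next
      n_cand <- stats::rpois(1, lmax * (t1 - t0))
      if (n_cand == 0) next
      tt <- sort(stats::runif(n_cand, t0, t1))
      idx <- pmin(ng, floor(tt * fs_grid_hz) + 1L)
      keep <- stats::runif(n_cand) < lam[idx] / lmax
      ts[[length(ts) + 1L]] <- tt[keep]
    }
    ts <- unlist(ts)
    if (is.null(ts)) ts <- numeric()
    ts <- ts[!duplicated(ts)]          # enforce strict increase
    spike_train(ts, unit_id = profile$unit_id)
  })
}

#' Generate a full synthetic nodule recording
#'
#' Convenience wrapper bundling background + interictal events, optional
#' seizures, and a set of gain-modulated units into one reproducible object.
#'
#' @param preset a [nodule_preset].
#' @param duration_s recording length (s).
#' @param fs_hz sampling rate (>= 1000).
#' @param profiles list of [unit_gain_profile]s.
#' @param n_seizures number of seizure epochs appended (sustained LFP + rate
#'   elevation).
#' @param seizure_dur_s seizure duration (s).
#' @param seed master seed; sub-seeds are derived deterministically.
#' @param ... passed to [generate_ip_series].
#' @return list of class `synth_recording`: `lfp`, `annotations`, `spikes`
#'   (list of [spike_train]), `events`, `profiles`, `seed`.
#' @export
generate_recording <- function(preset, duration_s, fs_hz = 1000,
                               profiles = list(), n_seizures = 0,
                               seizure_dur_s = 20, seed = 1, ...) {
  series <- generate_ip_series(preset, duration_s, fs_hz = fs_hz,
                               seed = seed, ...)
  ann <- series$annotations
  if (n_seizures > 0) {
    # place seizures uniformly in the final third, clear of each other
    starts <- with_seed(seed + 1000L, {
      lo <- 0.67 * duration_s
      sort(stats::runif(n_seizures, lo, duration_s - seizure_dur_s - 1))
    })
    sz <- annotation_table(label = rep("seizure", n_seizures),
                           channel_id = series$signal$channel_id,
                           start_s = starts, end_s = starts + seizure_dur_s)
    lfp <- series$signal$samples
    for (s in starts) { # sustained high-amplitude ictal rhythm
      seg <- fast_burst(12, seizure_dur_s, 180, fs_hz)
      lfp <- add_at(lfp, seg, round(s * fs_hz) + 1L)
    }
    series$signal$samples <- lfp
    ann <- validate_annotations(rbind(ann, sz))
  }
  spikes <- lapply(seq_along(profiles), function(i)
    generate_unit_spikes(ann, profiles[[i]], duration_s,
                         seed = seed + 2000L + i))
  structure(list(lfp = series$signal, annotations = ann, spikes = spikes,
                 events = series$events, profiles = profiles, seed = seed),
            class = "synth_recording")
}
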