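# Shared fixtures built in code at test time.

# Homogeneous Poisson spike train on [0, duration], independent of the
# package's thinning sampler (used as its oracle counterpart).
poisson_train <- function(rate_hz, duration_s, seed) {
  set.seed(seed)
  n <- rpois(1, rate_hz * duration_s)
  spike_train(sort(runif(n, 0, duration_s)))
}

# Trial matrix built directly from a matrix (bypassing epoch), for operations
# that only need the container.
tm_from_matrix <- function(data, fs = 1000, window = c(-2, 2), label = "PD+F",
                           pad_s = 0) {
  structure(list(
    data = data, fs_hz = fs, label = label, window_s = window,
    pad_s = pad_s, onsets_s = rep(0, nrow(data)),
    shifts_s = rep(0, nrow(data)),
    times_s = seq(round(window[1] * fs), round(window[2] * fs)) / fs,
    converged = TRUE), class = "trial_matrix")
}

# Binned Poisson rate matrices for the cluster test: trials x bins rates
# (spike counts over bin_w seconds divided by bin_w).
poisson_binned <- function(n_trials, n_bins, rate_hz, bin_w = 0.04) {
  matrix(rpois(n_trials * n_bins, rate_hz * bin_w) / bin_w, n_trials, n_bins)
}

# A small synthetic scenario reused across pipeline tests: ES series plus two
# activated units and one suppressed unit.
small_scenario <- function(seed = 101, duration_s = 420) {
  preset <- nodule_preset(1)
  profiles <- list(
    unit_gain_profile("act1", 8, list("ES" = gain_phasic(peak = 10)),
                      inverse = FALSE),
    unit_gain_profile("act2", 5, list("ES" = gain_sustained(peak = 6,
                                                            duration_s = 0.2)),
                      inverse = FALSE),
    unit_gain_profile("inv1", 12,
                      list("ES" = gain_inverse(floor_gain = 0,
                                               window_s = c(-0.2, 0.4))),
                      inverse = TRUE))
  generate_recording(preset, duration_s, profiles = profiles,
                     modes_s = c("ES" = 4), seed = seed)
}
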