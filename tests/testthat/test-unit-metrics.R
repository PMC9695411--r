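# biphasic extracellular spike template at fs, ~1 ms wide, unit trough depth
spike_template <- function(fs) {
  t <- seq(-0.0015, 0.0015, by = 1 / fs)
  -(exp(-(t)^2 / (2 * 0.0002^2)) - 0.45 * exp(-(t - 0.0006)^2 / (2 * 0.0004^2)))
}

test_that("MAD-threshold detection recovers injected spikes with few false alarms", {
  fs <- 32000
  set.seed(1)
  dur <- 20
  x <- rnorm(dur * fs)  # unit-SD wideband noise
  noise_sd <- median(abs(x)) / 0.6745
  # scale so the trough sits at 8x the noise scale AFTER the detection
  # high-pass (the filter attenuates the template's low-frequency tail)
  bf <- signal::butter(4, 300 / (fs / 2), type = "high")
  shape <- spike_template(fs)
  hp_trough <- min(signal::filtfilt(bf, c(numeric(fs / 10), shape,
                                          numeric(fs / 10))))
  tmpl <- shape * (8 * noise_sd / abs(hp_trough))
  truth <- seq(0.5, dur - 0.5, length.out = 200)
  for (s in truth) {
    i0 <- round(s * fs) - floor(length(tmpl) / 2)
    x[i0:(i0 + length(tmpl) - 1)] <- x[i0:(i0 + length(tmpl) - 1)] + tmpl
  }
  det <- detect_spikes(sampled_signal(x, fs), k_mad = 6)
  hit <- vapply(truth, function(s) any(abs(det$time_s - s) < 5e-4), TRUE)
  expect_gte(sum(hit), 195)
  matched <- vapply(det$time_s, function(d) any(abs(truth - d) < 5e-4), TRUE)
  expect_lte(sum(!matched), 5)
  expect_error(detect_spikes(sampled_signal(rnorm(1000), 1000)), "8000")
})

test_that("false positives on pure noise stay near the Gaussian crossing bound", {
  fs <- 32000; dur <- 10
  set.seed(2)
  det <- detect_spikes(sampled_signal(rnorm(dur * fs), fs), k_mad = 6)
  # Monte-Carlo oracle for the same crossing criterion on an independent
  # realization: high-pass shapes the noise, so calibrate on fresh noise
  # passed through the same rule coded directly
  bf <- signal::butter(4, 300 / (fs / 2), type = "high")
  oracle <- replicate(3, {
    y <- signal::filtfilt(bf, rnorm(dur * fs))
    thr <- 6 * median(abs(y)) / 0.6745
    sum(rle(y < -thr)$values)
  })
  expect_lte(nrow(det), max(oracle) * 3 + 10)
})

test_that("spikes inside annotated artifact periods are discarded", {
  fs <- 32000
  set.seed(3)
  x <- rnorm(5 * fs)
  tmpl <- spike_template(fs) * 10
  truth <- c(1, 2, 3, 4)
  for (s in truth) {
    i0 <- round(s * fs) - floor(length(tmpl) / 2)
    x[i0:(i0 + length(tmpl) - 1)] <- x[i0:(i0 + length(tmpl) - 1)] + tmpl
  }
  ann <- annotation_table("artifact", "u1", 1.9, 3.1)
  det <- detect_spikes(sampled_signal(x, fs), k_mad = 6, annotations = ann)
  expect_false(any(det$time_s > 1.9 & det$time_s < 3.1))
  expect_gte(sum(abs(outer(det$time_s, c(1, 4), "-")) < 5e-4), 2)
})

test_that("refractory-violation percentage matches hand counts and the Poisson law", {
  # ISIs 1, 10, 3, 1.5 ms: two of four violate the 2 ms refractory period
  t <- cumsum(c(0, 1, 10, 3, 1.5) / 1000)
  expect_equal(rpv(t), 50)
  # clock-like train: no violations
  expect_equal(rpv(seq(0, 10, by = 0.1)), 0)
  expect_error(rpv(0.5), "fewer than 2")
  # Poisson at 5 Hz: P(ISI < 2 ms) = 1 - exp(-0.01), about 1%
  tr <- poisson_train(5, 4000, seed = 4)
  p_true <- 100 * (1 - exp(-5 * 0.002))
  n_isi <- length(tr$times_s) - 1
  mc_sd <- 100 * sqrt(p_true / 100 * (1 - p_true / 100) / n_isi)
  expect_lt(abs(rpv(tr$times_s) - p_true), 4 * mc_sd)
})

test_that("SUA/MUA classification is a deterministic strict-threshold rule", {
  expect_equal(classify_unit(0.3, 8), "SUA")   # clean, large unit
  expect_equal(classify_unit(0.5, 6), "SUA")
  expect_equal(classify_unit(6.6, 8), "MUA")   # contaminated
  expect_equal(classify_unit(0.3, 2), "MUA")   # small-amplitude
  expect_equal(classify_unit(1.0, 8), "MUA")   # boundary: strict <
})

test_that("baseline windows exclude event overlap and yield FR and CV2", {
  # regular 4 Hz train, nothing to exclude
  tr <- spike_train(seq(0.125, 99.875, by = 0.25))
  bs <- baseline_stats(tr, annotation_table(), 100)
  expect_equal(bs$fr_hz, 4)
  expect_equal(bs$cv2, 0)
  expect_equal(bs$n_windows, 10L)

  # CV2 of a homogeneous Poisson train converges to 1
  trp <- poisson_train(8, 1500, seed = 5)
  bsp <- baseline_stats(trp, annotation_table(), 1500)
  expect_gt(length(trp$times_s), 10000)
  expect_lt(abs(bsp$cv2 - 1), 0.03)

  # annotations covering half the windows halve kept time, FR unbiased
  ann <- annotation_table(rep("seizure", 50), "u1",
                          start_s = seq(0, 980, by = 20) + 2,
                          end_s = seq(0, 980, by = 20) + 4)
  trl <- poisson_train(6, 1000, seed = 6)
  bsl <- baseline_stats(trl, ann, 1000)
  expect_equal(bsl$n_windows, 50L)
  expect_equal(bsl$kept_time_s, 500)
  expect_lt(abs(bsl$fr_hz - 6), 4 * sqrt(6 / 500))

  # nothing survives: explicit status, not an error
  allcov <- annotation_table("artifact", "u1", 0, 100)
  expect_equal(baseline_stats(tr, allcov, 100)$status, "no-windows")
})

test_that("CV2 is bounded in [0, 2] and zero only for equal consecutive ISIs", {
  set.seed(7)
  for (i in 1:20) {
    isi <- rexp(50, 5)
    v <- pnhmicro:::cv2_values(isi)
    expect_true(all(v >= 0 & v <= 2))
  }
  expect_true(all(pnhmicro:::cv2_values(rep(0.2, 10)) == 0))
  expect_gt(min(pnhmicro:::cv2_values(c(0.1, 0.2, 0.1))), 0)
})
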