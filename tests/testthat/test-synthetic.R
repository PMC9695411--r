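test_that("background noise hits the requested RMS and spectral slope", {
  # white case: sample SD equals the requested RMS
  bg <- generate_background(10, 1000, pink_exponent = 0, rms_uV = 10,
                            seed = 1)
  expect_equal(sd(bg$samples), 10, tolerance = 0.05)

  # pink case: log-log Welch slope ~ -1 over 1-100 Hz (independent PSD oracle)
  bg1 <- generate_background(30, 1000, pink_exponent = 1, rms_uV = 10,
                             seed = 2)
  ps <- spec.pgram(ts(bg1$samples, frequency = 1000), spans = 31,
                   plot = FALSE, taper = 0)
  sel <- ps$freq >= 1 & ps$freq <= 100
  slope <- unname(coef(lm(log(ps$spec[sel]) ~ log(ps$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.2)

  expect_error(generate_background(-1, 1000), "duration")
  expect_error(generate_background(10, 500), "fs_hz")
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_background(5, 1000, seed = 7)
  b <- generate_background(5, 1000, seed = 7)
  expect_identical(a$samples, b$samples)

  p <- nodule_preset(2)
  s1 <- generate_ip_series(p, 60, seed = 11)
  s2 <- generate_ip_series(p, 60, seed = 11)
  expect_identical(s1$signal$samples, s2$signal$samples)
  expect_identical(s1$annotations, s2$annotations)

  prof <- unit_gain_profile("u", 5, list("ES" = gain_phasic()))
  t1 <- generate_unit_spikes(s1$annotations, prof, 60, seed = 3)
  t2 <- generate_unit_spikes(s2$annotations, prof, 60, seed = 3)
  expect_identical(t1$times_s, t2$times_s)
})

test_that("rendered periodic trains honor period, jitter and ground truth", {
  p0 <- nodule_preset(1)
  p0$pdf_jitter_frac <- 0
  ev <- render_ip_event("PD+F", p0, seed = 1, n_deflections = 5)
  expect_length(ev$deflection_times_s, 5)
  expect_equal(diff(ev$deflection_times_s),
               rep(p0$pdf_period_s, 4), tolerance = 1e-12)
  # zero jitter: the ground-truth train is perfectly periodic
  rep0 <- periodicity_fraction(ev$deflection_times_s)
  expect_equal(rep0$pct, 100L)
  expect_true(rep0$periodic)

  expect_error(render_ip_event("PD+F", p0, n_deflections = 2), "three")
  expect_error(render_ip_event("SD+F", nodule_preset(3)), "no SD\\+F")
})

test_that("rendered ES segment has its fast-activity peak at the preset frequency", {
  p <- nodule_preset(1)
  # average periodograms over phase-randomized renders; 5 Hz bins (200 ms)
  set.seed(4)
  nseg <- 200; wlen <- 200
  taper <- 0.5 * (1 - cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1)))
  freqs <- seq(60, 200, by = 5)
  basis <- exp(-2i * pi * outer((seq_len(wlen) - 1) / 1000, freqs))
  pow <- numeric(length(freqs))
  for (i in seq_len(nseg)) {
    ev <- render_ip_event("ES", p)
    seg <- ev$samples[seq_len(wlen)] * taper
    pow <- pow + Mod(crossprod(seg, basis))^2
  }
  # remove the sharp-transient broadband floor: peak must sit at es_fast_hz
  expect_lte(abs(freqs[which.max(pow)] - p$es_fast_hz), 5)
})

test_that("event series conserves counts and recovers the interval mode", {
  p <- nodule_preset(1)
  # zero rate: annotations empty, signal equals background
  s0 <- generate_ip_series(p, 20, modes_s = c("ES" = 0), seed = 5)
  expect_equal(nrow(s0$annotations), 0L)
  bg <- generate_background(20, 1000, pink_exponent = 1, rms_uV = 10, seed = 5)
  expect_identical(s0$signal$samples, bg$samples)

  # count conservation: one annotation row per inserted event, right label
  s1 <- generate_ip_series(p, 300, modes_s = c("ES" = 2), seed = 6)
  expect_equal(nrow(s1$annotations), length(s1$events))
  expect_true(all(s1$annotations$label == "ES"))
  expect_true(all(s1$annotations$start_s >= 0 &
                    s1$annotations$end_s <= 300))
  # same-kind events never overlap
  on <- s1$annotations$start_s; off <- s1$annotations$end_s
  expect_true(all(on[-1] >= off[-length(off)]))

  # interval mode recovered within one histogram bin
  s2 <- generate_ip_series(p, 3000, modes_s = c("ES" = 4), sigma_log = 0.5,
                           seed = 7)
  im <- interval_mode(s2$annotations$start_s, bin_width_s = 1)
  expect_lte(abs(im$lambda_mode_s - 4), 1)
})

test_that("unit spike sampling matches the inhomogeneous-Poisson law", {
  empty <- annotation_table()
  prof <- unit_gain_profile("u", 5, list())
  tr <- generate_unit_spikes(empty, prof, 1000, seed = 8)
  # g = 1 everywhere: count within 3 SD of rate * duration
  expect_lt(abs(length(tr$times_s) - 5000), 3 * sqrt(5000))
  expect_false(is.unsorted(tr$times_s, strictly = TRUE))

  # inverse unit with g = 0: no spikes inside any suppression window
  ann <- annotation_table(rep("ES", 50), "u1",
                          start_s = seq(5, 495, by = 10),
                          end_s = seq(5, 495, by = 10) + 0.2)
  prof0 <- unit_gain_profile("inv", 20,
                             list("ES" = gain_inverse(0, c(-0.25, 0.25))))
  tri <- generate_unit_spikes(ann, prof0, 500, seed = 9)
  inside <- vapply(tri$times_s, function(s)
    any(s >= ann$start_s - 0.25 & s < ann$start_s + 0.25), TRUE)
  expect_equal(sum(inside), 0L)

  # total count matches the integral of lambda(t)
  prof5 <- unit_gain_profile("g5", 4,
                             list("ES" = gain_sustained(5, 0, 1)))
  tr5 <- generate_unit_spikes(ann, prof5, 500, seed = 10)
  lam <- unit_rate_on_grid(prof5, ann, 500)
  expected <- sum(lam) / 1000
  expect_lt(abs(length(tr5$times_s) - expected), 4 * sqrt(expected))
})

test_that("presets carry the per-nodule fast-activity frequencies", {
  expect_equal(vapply(1:4, function(i) nodule_preset(i)$pdf_fast_hz, 0),
               c(92, 135, 106, 81))
  expect_equal(vapply(1:4, function(i) nodule_preset(i)$es_fast_hz, 0),
               c(102, 134, 121, 97))
  expect_equal(nodule_preset(1)$sdf_fast_hz, 96)
  expect_equal(nodule_preset(2)$sdf_fast_hz, 111)
  expect_true(is.na(nodule_preset(3)$sdf_fast_hz))
  expect_equal(nodule_preset(4)$sdf_fast_hz, 77)
  # the nodule-2 SD+F mapping stays overridable
  expect_equal(nodule_preset(2, sdf_fast_hz = 105)$sdf_fast_hz, 105)
})
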