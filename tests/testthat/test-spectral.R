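sinusoid_tm <- function(freq, ntrials = 3, window = c(-2, 2), fs = 1000,
                        amp = 1) {
  t <- seq(window[1], window[2], by = 1 / fs)
  tm_from_matrix(matrix(rep(amp * sin(2 * pi * freq * t), ntrials),
                        ntrials, byrow = TRUE), fs = fs, window = window)
}

test_that("the Hanning TFR concentrates sinusoidal power at the right bin", {
  tm <- sinusoid_tm(100)
  tfr <- compute_tfr(tm, window_s = 0.4)
  expect_equal(diff(tfr$times_s[1:2]), 0.005)           # 5 ms steps
  expect_equal(diff(tfr$freqs_hz[1:2]), 2.5)            # 1/window resolution
  spec <- rowMeans(tfr$power)
  expect_lte(abs(tfr$freqs_hz[which.max(spec)] - 100), 2.5)
  # power is constant over time within 5%
  p100 <- tfr$power[which.max(spec), ]
  expect_lt((max(p100) - min(p100)) / mean(p100), 0.05)

  # zero signal: all power zero
  tm0 <- tm_from_matrix(matrix(0, 3, 4001))
  expect_true(all(compute_tfr(tm0, window_s = 0.4)$power == 0))

  # two summed sinusoids give two distinct peaks, each within one bin
  t <- seq(-2, 2, by = 1e-3)
  tm2 <- tm_from_matrix(matrix(rep(sin(2 * pi * 80 * t) +
                                     sin(2 * pi * 160 * t), 3),
                               3, byrow = TRUE))
  spec2 <- rowMeans(compute_tfr(tm2, window_s = 0.4)$power)
  f <- seq(60, 200, by = 2.5)
  lo <- f[f < 120][which.max(spec2[f < 120])]
  hi <- f[f >= 120][which.max(spec2[f >= 120])]
  expect_lte(abs(lo - 80), 2.5)
  expect_lte(abs(hi - 160), 2.5)

  expect_error(compute_tfr(tm_from_matrix(matrix(0, 2, 100),
                                          window = c(0, 0.099)),
                           window_s = 0.4), "longer")
})

test_that("baseline normalization is zero-mean on its own window and exact on steps", {
  # stationary noise: % change fluctuates around 0
  set.seed(1)
  tm <- tm_from_matrix(matrix(rnorm(120 * 4001), 120))
  tfr <- baseline_normalize(compute_tfr(tm, window_s = 0.4),
                            baseline_window_s = c(-2, -1))
  inb <- tfr$times_s >= -2 & tfr$times_s <= -1
  # exact zero on the baseline window by construction
  expect_equal(max(abs(rowMeans(tfr$power[, inb]))), 0, tolerance = 1e-9)
  # small everywhere for stationary input: the per-frequency offset is driven
  # by baseline sampling noise, SE ~ 100 / sqrt(trials x indep. baseline
  # windows); bound the worst frequency at 3 SE
  se_pct <- 100 / sqrt(120 * (1 / 0.4))
  expect_lt(max(abs(rowMeans(tfr$power))), 3 * se_pct)

  # power doubled in a window -> about +100% there (amplitude x sqrt 2)
  t <- seq(-2, 2, by = 1e-3)
  x <- sin(2 * pi * 100 * t)
  x[t >= 0.5 & t < 1.5] <- sqrt(2) * x[t >= 0.5 & t < 1.5]
  tmd <- tm_from_matrix(matrix(rep(x, 4), 4, byrow = TRUE))
  tfd <- baseline_normalize(compute_tfr(tmd, window_s = 0.4),
                            baseline_window_s = c(-2, -1))
  k100 <- which(tfd$freqs_hz == 100)
  mid <- tfd$times_s >= 0.8 & tfd$times_s <= 1.2
  expect_equal(mean(tfd$power[k100, mid]), 100, tolerance = 2)

  # synthetic ES: positive % change localized to the burst epoch
  ser <- generate_ip_series(nodule_preset(1), 200, modes_s = c("ES" = 2),
                            seed = 2)
  tme <- align_trials(epoch(ser$signal, ser$annotations, "ES"))
  tfe <- baseline_normalize(compute_tfr(tme))
  k <- which.min(abs(tfe$freqs_hz - 100))
  during <- tfe$times_s >= 0 & tfe$times_s <= 0.2
  before <- tfe$times_s >= -0.9 & tfe$times_s <= -0.5
  expect_gt(mean(tfe$power[k, during]), 10 * max(1, mean(tfe$power[k, before])))

  expect_error(baseline_normalize(compute_tfr(sinusoid_tm(100)),
                                  baseline_window_s = c(5, 6)), "outside")
})

test_that("band averaging equals a hand-summed oracle", {
  tm <- sinusoid_tm(100)
  tfr <- compute_tfr(tm, window_s = 0.4)
  # uniform +50% map: band average +50 everywhere
  tfr2 <- tfr; tfr2$power[] <- 50
  expect_true(all(band_average(tfr2) == 50))
  # direct-sum oracle on a synthetic % map
  set.seed(3)
  tfr3 <- tfr; tfr3$power <- matrix(rnorm(length(tfr$power)),
                                    nrow(tfr$power))
  inb <- tfr3$freqs_hz >= 90 & tfr3$freqs_hz <= 110
  oracle <- apply(tfr3$power[inb, , drop = FALSE], 2, function(col)
    sum(col) / length(col))
  expect_equal(band_average(tfr3, c(90, 110)), oracle)
  expect_error(band_average(tfr3, c(300, 400)), "outside")
})

test_that("peak frequency extraction uses argmax with a lowest-frequency tie rule", {
  tm <- sinusoid_tm(100)
  tfr <- compute_tfr(tm, window_s = 0.4)  # raw power: stationary tone
  pk <- peak_frequency(tfr, analysis_window_s = c(-0.5, 0.5))
  expect_lte(abs(pk$f_peak_hz - 100), 2.5)
  # flat spectrum: lowest frequency wins
  tfr0 <- tfr; tfr0$power[] <- 1
  expect_equal(peak_frequency(tfr0)$f_peak_hz, min(tfr0$freqs_hz))
  expect_error(peak_frequency(tfr, analysis_window_s = c(10, 11)), "outside")
})

test_that("white-signal windowed power is flat across frequency", {
  set.seed(4)
  tm <- tm_from_matrix(matrix(rnorm(220 * 4001), 220))
  spec <- rowMeans(compute_tfr(tm, window_s = 0.4)$power)
  expect_lt(max(abs(spec - mean(spec))) / mean(spec), 0.1)
})
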