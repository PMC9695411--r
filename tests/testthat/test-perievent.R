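test_that("kernel rate has the Gaussian closed form and conserves spike counts", {
  tr <- spike_train(0)
  per <- kernel_rate(tr, onsets_s = 0, window_s = c(-1, 1), sigma_s = 0.010)
  k0 <- which(per$times_s == 0)
  expect_equal(per$rate[1, k0], 1 / (0.010 * sqrt(2 * pi)), tolerance = 1e-6)

  # integral over the window ~ spike count for spikes away from edges
  set.seed(1)
  spikes <- sort(runif(40, -0.8, 0.8))
  tr2 <- spike_train(spikes)
  per2 <- kernel_rate(tr2, 0, window_s = c(-1, 1), sigma_s = 0.010)
  expect_equal(sum(per2$rate[1, ]) / 1000, 40, tolerance = 0.01 * 40)

  # empty train: all-zero rates, not an error
  per0 <- kernel_rate(spike_train(numeric()), c(0, 10), c(-1, 1), 0.01)
  expect_true(all(per0$rate == 0))
})

test_that("peri-event gain is recovered from generator ground truth", {
  ann <- annotation_table(rep("SD+F", 100), "u1",
                          start_s = seq(10, 1000, by = 10),
                          end_s = seq(10, 1000, by = 10) + 1)
  prof <- unit_gain_profile("g5", 6, list("SD+F" = gain_sustained(5, 0, 1)))
  tr <- generate_unit_spikes(ann, prof, 1010, seed = 2)
  per <- kernel_rate(tr, ann$start_s, window_s = c(-2, 2), sigma_s = 0.050)
  av <- avg_rate(per)
  plateau <- per$times_s >= 0.2 & per$times_s <= 0.8
  base <- per$times_s >= -2 & per$times_s <= -1
  expect_equal(mean(av[plateau]) / mean(av[base]), 5, tolerance = 0.10)
})

test_that("binning equals direct sums and conserves the integrated rate", {
  set.seed(3)
  tr <- poisson_train(20, 50, seed = 3)
  per <- kernel_rate(tr, c(10, 20, 30), window_s = c(-2, 2), sigma_s = 0.05)
  binned <- bin_rates(per, 100)
  expect_equal(dim(binned), c(3, 100))
  # constant rate stays constant
  perc <- per; perc$rate[] <- 10
  expect_true(all(abs(bin_rates(perc, 100) - 10) < 1e-12))
  # brute-force bin means over the 1 ms samples
  bw <- 0.04
  grp <- pmin(100, floor((per$times_s + 2) / bw) + 1)  # same edge convention
  oracle <- t(sapply(1:3, function(i)
    sapply(1:100, function(b) {
      acc <- 0; cnt <- 0
      for (j in which(grp == b)) { acc <- acc + per$rate[i, j]; cnt <- cnt + 1 }
      acc / cnt
    })))
  expect_equal(unclass(binned)[, ], oracle, ignore_attr = TRUE)
  # conservation: sum(bin mean x bin width) ~ integral of the rate
  expect_equal(rowSums(binned) * bw, rowSums(per$rate) / 1000,
               tolerance = 0.02)
})

test_that("rate-LFP correlation has the right sign structure and null scale", {
  x <- sin(seq(0, 10, by = 0.01))
  expect_equal(rate_lfp_correlation(3 * x + 2, x)$rho, 1)
  expect_equal(rate_lfp_correlation(-2 * x + 1, x)$rho, -1)
  expect_equal(rate_lfp_correlation(rep(1, 100), rnorm(100))$status,
               "zero-variance")
  expect_error(rate_lfp_correlation(1:5, 1:6), "time axis")
  # independent noise: |rho| < 3/sqrt(n) in at least ~95% of draws
  set.seed(4)
  n <- 400
  hits <- replicate(200, abs(rate_lfp_correlation(rnorm(n), rnorm(n))$rho) <
                      3 / sqrt(n))
  expect_gte(mean(hits), 0.93)
})

test_that("modulation percentages use significant clusters with n.s. propagation", {
  # deterministic construction: 3x baseline plateau in a known window
  set.seed(5)
  ntr <- 60
  binned <- poisson_binned(ntr, 100, 10, bin_w = 0.4)
  binned[, 41:60] <- matrix(rpois(ntr * 20, 30 * 0.4) / 0.4, ntr, 20)
  attr(binned, "bin_centers_s") <- seq(-2 + 0.02, 2, by = 0.04)
  attr(binned, "bin_width_s") <- 0.04
  centers <- attr(binned, "bin_centers_s")
  bl <- binned[, centers >= -2 & centers <= -1]
  cres <- cluster_permutation_test(binned, bl, n_perm = 2000, seed = 6)
  mod <- modulation_percent(binned, cres, label = "PD+F")
  expect_true(mod$up_sig)
  expect_equal(mod$up_pct, 200, tolerance = 0.15 * 200)

  # complete silence in a significant window: down = 100%
  b2 <- poisson_binned(ntr, 100, 10, bin_w = 0.4)
  b2[, 41:60] <- 0
  attr(b2, "bin_centers_s") <- centers
  cres2 <- cluster_permutation_test(b2, b2[, centers <= -1], n_perm = 2000,
                                    seed = 7)
  mod2 <- modulation_percent(b2, cres2, label = "PD+F")
  expect_true(mod2$down_sig)
  expect_equal(mod2$down_pct, 100, tolerance = 3)

  # no significant clusters: explicit n.s., never zero
  b3 <- poisson_binned(ntr, 100, 10, bin_w = 0.4)
  attr(b3, "bin_centers_s") <- centers
  cres3 <- cluster_permutation_test(b3, b3[, centers <= -1], n_perm = 2000,
                                    seed = 8)
  mod3 <- modulation_percent(b3, cres3, label = "PD+F")
  if (!mod3$up_sig) expect_true(is.na(mod3$up_pct))
  if (!mod3$down_sig) expect_true(is.na(mod3$down_pct))
})

test_that("seizure rasters are descriptive and recover ictal gain", {
  onsets <- seq(100, 1200, by = 100)  # 12 seizures
  ann <- annotation_table(rep("seizure", 12), "u1", onsets, onsets + 20)
  prof3 <- unit_gain_profile("ict", 5, list("seizure" = gain_ictal(3)))
  prof1 <- unit_gain_profile("flat", 5, list())
  tr3 <- generate_unit_spikes(ann, prof3, 1250, seed = 9)
  tr1 <- generate_unit_spikes(ann, prof1, 1250, seed = 10)
  sr <- seizure_raster(list(tr3, tr1), onsets, window_s = c(-20, 20))
  expect_length(sr$raster[["ict"]], 12)
  expect_length(sr$raster[["flat"]], 12)
  # sustained 3x ictal gain: post/pre rate ratio ~ 3 within 20%
  r3 <- sr$summary$ratio[sr$summary$unit_id == "ict"]
  expect_equal(r3, 3, tolerance = 0.2 * 3)
  r1 <- sr$summary$ratio[sr$summary$unit_id == "flat"]
  expect_equal(r1, 1, tolerance = 0.2)
  # empty train: empty raster rows
  sre <- seizure_raster(spike_train(numeric(), "none"), onsets)
  expect_true(all(lengths(sre$raster[["none"]]) == 0))
})
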