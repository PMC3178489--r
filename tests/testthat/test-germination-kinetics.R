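test_that("Dv50 follows the log-interpolated midpoint convention", {
  expect_equal(median_diameter(c(0, 1, 0), c(1, 3, 10)), 3)      # monodisperse
  expect_equal(median_diameter(c(0.5, 0.5), c(10, 1000)), 100)   # geometric midpoint
  ## bounded by the occupied support
  set.seed(1)
  for (i in 1:20) {
    v <- runif(30); v <- v / sum(v)
    d <- sort(runif(30, 1, 2000))
    m <- median_diameter(v, d)
    expect_gte(m, min(d))
    expect_lte(m, max(d))
  }
  expect_error(median_diameter(c(0, 0), c(1, 2)), "all-zero")
})

test_that("Sauter mean diameter equals its number-weighted form", {
  expect_equal(sauter_mean_diameter(c(1), c(7)), 7)              # identity
  expect_equal(sauter_mean_diameter(c(0.5, 0.5), c(1, 3)), 1.5)  # hand value
  set.seed(2)
  for (i in 1:100) {
    v <- runif(40); v <- v / sum(v)
    d <- sort(exp(runif(40, 0, 7)))
    smd <- sauter_mean_diameter(v, d)
    n <- v / d^3                       # counts from volume fractions
    oracle <- sum(n * d^3) / sum(n * d^2)
    expect_lt(abs(smd - oracle), 1e-9 * oracle)
  }
})

test_that("Dv50 and D[3,2] are stable under bin refinement", {
  ## smooth lognormal volume distribution sampled on 100 vs 200 bins
  for (n_bins in c(100L, 200L)) {
    b <- psd_bins(n_bins)
    v <- dlnorm(b$centers, log(50), 0.6)
    v <- v / sum(v)
    assign(paste0("m", n_bins), median_diameter(v, b$centers))
    assign(paste0("s", n_bins), sauter_mean_diameter(v, b$centers))
  }
  expect_lt(abs(m200 - m100) / m100, 0.01)
  expect_lt(abs(s200 - s100) / s100, 0.01)
})

test_that("SMD lags the median on germination series and the QC check is honest", {
  ser <- simulate_germination_psd(germination_scenario(seed = 8))
  expect_true(smd_lags_median(ser))

  ## degenerate equality: monodisperse at all times
  bins <- psd_bins(30)
  vf <- matrix(0, 10, 30); vf[, 12] <- 1
  flat <- size_distribution_series(seq(0, 9 * 285, by = 285), bins$centers, vf)
  expect_true(smd_lags_median(flat))

  ## adversarial: a series ending in a half-and-half mixture. The SMD's final
  ## value (harmonic-type mean, ~6 um) sits much lower than the median's
  ## (geometric midpoint, ~55 um), so the SMD reaches its own half-rise level
  ## (w ~ 0.34) one snapshot before the median reaches its (w ~ 0.39).
  times <- seq(0, 9 * 285, by = 285)
  w_hi <- c(0, 0, 0.1, 0.2, 0.3, 0.35, 0.4, 0.45, 0.5, 0.5)
  ser2 <- two_bin_series(times, c(3, 1000), w_hi)
  expect_false(smd_lags_median(ser2))
})

test_that("onset detection finds abrupt median jumps and errors without one", {
  st <- step_psd_series(t_step_s = 300 * 60)
  onset <- detect_onset(st)
  ## first post-step timestamp
  expect_equal(onset, min(st$times_s[st$times_s >= 300 * 60]) / 60)

  flat <- step_psd_series(t_step_s = 1e9)    # never steps
  expect_error(detect_onset(flat), "no germination detected")

  sim <- simulate_germination_psd(
    germination_scenario(lag_sd_min = 0, lag_mean_min = 250, seed = 3))
  truth <- attr(sim, "ground_truth")
  expect_lt(abs(detect_onset(sim) - truth$onset_min), 285 / 60 + 1e-9)
})

test_that("plateau detection finds SMD stabilisation and rejects rising series", {
  st <- step_psd_series(t_step_s = 300 * 60)
  expect_equal(detect_plateau(st),
               min(st$times_s[st$times_s >= 300 * 60]) / 60)

  ## linearly rising SMD with no flattening
  bins <- psd_bins(80)
  times <- seq(0, 99 * 285, by = 285)
  d <- seq(5, 2000, length.out = length(times))
  bi <- findInterval(d, bins$edges)
  vf <- matrix(0, length(times), 80)
  vf[cbind(seq_along(times), bi)] <- 1
  rising <- size_distribution_series(times, bins$centers, vf)
  expect_error(detect_plateau(rising), "ended before plateau")

  sim <- simulate_germination_psd(germination_scenario(seed = 5))
  truth <- attr(sim, "ground_truth")
  expect_lt(abs(detect_plateau(sim) - truth$t90_min), 2 * 285 / 60)
})

test_that("germination summary composes onset and plateau", {
  st <- step_psd_series(t_step_s = 300 * 60)
  est <- germination_summary(st)
  expect_equal(est$germination_time_min, 0)
  expect_equal(est$lag_phase_min, est$onset_time_min)
  expect_equal(est$plateau_time_min - est$onset_time_min,
               est$germination_time_min)
  expect_equal(est$baseline_median_um, 3, tolerance = 0.2)
  expect_equal(est$plateau_median_um, 1000, tolerance = 0.1)
  expect_named(est$detection_params,
               c("baseline_window", "jump_factor", "persistence",
                 "plateau_quantile", "plateau_tolerance"))
})

test_that("wider lag distributions give longer germination times", {
  for (seed in 1:5) {
    dt <- sapply(c(20, 80), function(sd) {
      ser <- simulate_germination_psd(
        germination_scenario(lag_sd_min = sd, seed = seed))
      germination_summary(ser)$germination_time_min
    })
    expect_gt(dt[2], dt[1])
  }
})

test_that("lag phase rises across an osmolality-like panel of lag means", {
  lag_means <- seq(150, 500, length.out = 5)  # emulating 0.35 -> 3.6 osmol/kg
  lags <- sapply(seq_along(lag_means), function(i) {
    ser <- simulate_germination_psd(
      germination_scenario(lag_mean_min = lag_means[i], seed = 40 + i))
    germination_summary(ser)$lag_phase_min
  })
  expect_true(all(diff(lags) > 0))
})

test_that("series validation enforces the container invariants", {
  bins <- psd_bins(10)
  good <- matrix(1 / 10, 2, 10)
  expect_s3_class(size_distribution_series(c(0, 285), bins$centers, good),
                  "fm_psd_series")
  expect_error(size_distribution_series(c(285, 0), bins$centers, good),
               "strictly increasing")
  bad <- good; bad[1, 1] <- 0.5
  expect_error(size_distribution_series(c(0, 285), bins$centers, bad),
               "sum to 1")
  neg <- good; neg[1, 1] <- -0.1; neg[1, 2] <- 0.3
  expect_error(size_distribution_series(c(0, 285), bins$centers, neg),
               "negative")
})
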