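test_that("BDWI reproduces rectangle and triangle integrals and is nondecreasing", {
  rect <- cultivation_record(0:10, rep(3, 11), rep(1, 11))
  expect_equal(bdwi(rect), 3 * (0:10))
  tri <- cultivation_record(0:10, 2 * (0:10), rep(1, 11))
  expect_equal(bdwi(tri)[11], 2 * 10^2 / 2)
  expect_equal(bdwi(tri)[1], 0)
  set.seed(4)
  noisy <- cultivation_record(0:20, runif(21, 0, 5), rep(1, 21))
  expect_true(all(diff(bdwi(noisy)) >= 0))
})

test_that("specific productivity is the OLS slope of activity over BDWI", {
  ## exact when activity is built from the trapezoidal BDWI itself
  t <- seq(0, 72, length.out = 25)
  x <- logistic_biomass(t, 0.16, 0.01, 4)
  b <- bdwi(cultivation_record(t, x, rep(1, 25)))
  rec <- cultivation_record(t, x, 3.5 * b + 2)
  expect_equal(specific_productivity(rec)$specific_productivity_U_mg_h, 3.5,
               tolerance = 1e-9)
  expect_equal(specific_productivity(rec)$slope_r2, 1, tolerance = 1e-12)
  ## flat activity -> zero slope
  flat <- cultivation_record(0:10, rep(2, 11), rep(7, 11))
  expect_equal(specific_productivity(flat)$specific_productivity_U_mg_h, 0,
               tolerance = 1e-12)
  ## all-zero biomass -> degenerate regressor
  degen <- cultivation_record(0:10, rep(0, 11), 0:10)
  expect_error(specific_productivity(degen), "degenerate regressor")
})

test_that("specific productivity recovers the truth within 3% at 5% noise", {
  sl <- sapply(1:20, function(s) {
    rec <- simulate_cultivation(cultivation_scenario(
      q_p_U_mg_h = 2, noise_cv = 0.05, n_samples = 50, seed = s))
    specific_productivity(rec)$specific_productivity_U_mg_h
  })
  expect_lt(abs(mean(sl) - 2) / 2, 0.03)
})

test_that("specific productivity is invariant to consistent time-unit rescaling", {
  rec_h <- simulate_cultivation(cultivation_scenario(q_p_U_mg_h = 2,
                                                     noise_cv = 0, seed = 1))
  rec_min <- cultivation_record(rec_h$time_h * 60, rec_h$bdw_g_L,
                                rec_h$activity_U_mL)
  slope_h <- specific_productivity(rec_h)$specific_productivity_U_mg_h
  slope_min <- specific_productivity(rec_min)$specific_productivity_U_mg_h
  expect_equal(slope_min * 60, slope_h, tolerance = 1e-9)
})

test_that("mu_max recovers exponential, logistic and flat growth", {
  t <- 0:30
  expo <- cultivation_record(t, 0.01 * exp(0.16 * t), rep(1, 31))
  expect_equal(mu_max(expo), 0.16, tolerance = 1e-12)

  logi <- simulate_cultivation(cultivation_scenario(
    mu_max_per_h = 0.16, noise_cv = 0, t_end_h = 72, n_samples = 73, seed = 1))
  expect_lt(abs(mu_max(logi) - 0.16) / 0.16, 0.05)

  flat <- cultivation_record(0:10, rep(2, 11), rep(1, 11))
  expect_equal(mu_max(flat), 0, tolerance = 1e-12)

  zero <- cultivation_record(0:10, rep(0, 11), rep(1, 11))
  expect_error(mu_max(zero), "positive biomass")
})

test_that("fold and percent change reproduce the worked arithmetic", {
  expect_equal(percent_change(88.8, 98.4), 10.8, tolerance = 2e-3)
  expect_equal(fold_change(0.5, 9), 18)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(fold_change(5, 5), 1)
  expect_error(fold_change(0, 1), "positive")
})

test_that("exponential fitter achieves machine-precision recovery on a grid", {
  x <- seq(0.1, 1, length.out = 20)
  for (a in c(0.1, 1, 10, 100)) {
    for (b in c(-6, -3, 0, 3)) {
      fit <- fit_exponential(x, a * exp(b * x))
      expect_lt(abs(fit$a - a) / a, 1e-6)
      expect_lt(abs(fit$b - b), 1e-6)
      if (b != 0) expect_gt(fit$r2, 1 - 1e-9)
    }
  }
})

test_that("exponential fitter handles degenerate inputs per contract", {
  x <- seq(0, 1, length.out = 10)
  fit <- fit_exponential(x, rep(4, 10))
  expect_equal(fit$a, 4, tolerance = 1e-9)
  expect_equal(fit$b, 0, tolerance = 1e-9)
  expect_error(fit_exponential(rep(0.5, 5), 1:5), "singular design")
  expect_error(fit_exponential(x, c(rep(1, 9), -1)), "nonpositive y")
  expect_error(fit_exponential(c(0, 1), c(1, 2)), "insufficient")
})

test_that("panel correlation joins, excludes mycelial cultivations and fits", {
  panel <- data.frame(
    morphology_number = c(0.8, 0.6, 0.4, 0.2, NA),
    specific_productivity = c(6.83 * exp(-2.94 * c(0.8, 0.6, 0.4, 0.2)), 9),
    mycelial = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  expect_message(res <- correlate_panel(panel), "excluding 1 mycelial")
  expect_equal(res$fit$b, -2.94, tolerance = 1e-6)
  expect_equal(nrow(res$scatter), 4)

  expect_error(suppressMessages(correlate_panel(panel[c(1, 2, 5), ])),
               "insufficient")
  same <- data.frame(morphology_number = rep(0.5, 4),
                     specific_productivity = c(1, 2, 3, 4),
                     mycelial = FALSE)
  expect_error(correlate_panel(same), "singular design")
})

test_that("productivity_result bundles the performance metrics", {
  rec <- simulate_cultivation(cultivation_scenario(q_p_U_mg_h = 2,
                                                   noise_cv = 0,
                                                   n_samples = 200, seed = 1))
  pr <- productivity_result(rec)
  expect_equal(pr$specific_productivity_U_mg_h, 2, tolerance = 1e-4)
  expect_equal(pr$final_activity_U_mL, rec$activity_U_mL[nrow(rec)])
  expect_true(all(diff(pr$bdwi_curve$bdwi_g_h_L) >= 0))
})
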