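test_that("simulated medians converge to the analytic quantile without variability", {
  m <- population_model("loglogistic", Te_pop = 27.47, p_pop = 3.5, sigma = 1)
  scn <- simulation_scenario(m, n_replicates = 50,
                             subjects_per_replicate = 10000, seed = 3)
  sm <- simulate_scenario(scn)
  expect_equal(sm$median$point, 27.47, tolerance = 0.02)
  expect_lte(sm$median$lower, sm$median$point)
  expect_gte(sm$median$upper, sm$median$point)
  m2 <- population_model("weibull", Te_pop = 41.69, p_pop = 2.25, sigma = 1)
  sm2 <- simulate_scenario(simulation_scenario(m2, n_replicates = 50,
                                               subjects_per_replicate = 10000,
                                               seed = 4))
  expect_equal(sm2$median$point, 41.69 * log(2)^(1 / 2.25), tolerance = 0.02)
})

test_that("scenario runs are reproducible and internally consistent", {
  m <- reference_models()$os_first_line_final
  mix <- data.frame(weight = c(0.62, 0.38), race_nonasian = c(0, 1))
  scn <- simulation_scenario(m, mix, n_replicates = 100,
                             subjects_per_replicate = 100, seed = 17)
  a <- simulate_scenario(scn)
  b <- simulate_scenario(scn)
  expect_identical(a$median, b$median)
  expect_identical(a$landmark_rates, b$landmark_rates)
  # landmark rates nonincreasing in t, inside [0, 1], band order preserved
  expect_true(all(diff(a$landmark_rates$rate) <= 0))
  expect_true(all(a$landmark_rates$rate >= 0 & a$landmark_rates$rate <= 1))
  expect_true(all(a$percentile_bands$p10 <= a$percentile_bands$p50 + 1e-12))
  expect_true(all(a$percentile_bands$p50 <= a$percentile_bands$p90 + 1e-12))
  expect_true(all(a$landmark_rates$lower <= a$landmark_rates$rate + 1e-12))
  expect_true(all(a$landmark_rates$upper >= a$landmark_rates$rate - 1e-12))
})

test_that("CI width shrinks with larger replicate cohorts", {
  m <- reference_models()$os_first_line_final
  widths <- vapply(c(50, 400), function(n) {
    sm <- simulate_scenario(simulation_scenario(m, NULL, n_replicates = 200,
                                                subjects_per_replicate = n,
                                                seed = 23))
    sm$median$upper - sm$median$lower
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("landmark rates average the mixture exactly when omega = 0", {
  m <- population_model("weibull", Te_pop = 41.69, p_pop = 2.25,
                        theta_cov = c(race_nonasian = 0.19), sigma = 1)
  mix <- data.frame(weight = c(0.62, 0.38), race_nonasian = c(0, 1))
  expect_equal(landmark_rate(m, mix, 0), 1)
  r36 <- landmark_rate(m, mix, 36)
  s_as <- exp(-(36 / 41.69)^2.25)
  s_na <- exp(-(36 / (41.69 * exp(0.19)))^2.25)
  expect_equal(r36, 0.62 * s_as + 0.38 * s_na, tolerance = 1e-12)
  # published closed-form cross-check: Asian-only 3-year rate ~ 0.487
  expect_equal(landmark_rate(m, data.frame(weight = 1, race_nonasian = 0), 36),
               exp(-(36 / 41.69)^2.25), tolerance = 1e-12)
  expect_equal(exp(-(36 / 41.69)^2.25), 0.487, tolerance = 1e-3)
})

test_that("quadrature and Monte Carlo random-effect averaging agree", {
  m <- reference_models()$os_first_line_final
  mix <- data.frame(weight = c(0.62, 0.38), race_nonasian = c(0, 1))
  rq <- landmark_rate(m, mix, c(12, 36, 60))
  rmc <- landmark_rate(m, mix, c(12, 36, 60), method = "mc",
                       n_draws = 200000, seed = 8)
  expect_equal(rq, rmc, tolerance = 0.01)
  expect_true(all(diff(rq) < 0))
})

test_that("VPC is calibrated on self-generated data and degrades when misspecified", {
  data <- make_obs_dataset(n_studies = 8, seed = 83)
  ft <- fit_tte(data, "weibull", standard_errors = FALSE)
  rep_ok <- vpc(ft, data, n_sim = 200, seed = 9)
  expect_gte(rep_ok$frac_in_band, 0.7)
  # deliberately wrong family and parameters: coverage collapses
  bad <- population_model("gompertz", Te_pop = 15, p_pop = 0.3,
                          omega_Te = 0.05, omega_p = 0.05, sigma = 0.3)
  rep_bad <- vpc(bad, data, n_sim = 200, seed = 9)
  expect_lt(rep_bad$frac_in_band, rep_ok$frac_in_band)
  # degenerate single simulation gives collapsed bands
  rep1 <- vpc(ft, data, n_sim = 1, seed = 10)
  expect_equal(rep1$table$q10, rep1$table$q90)
})

test_that("goodness of fit reports near-perfect R2 in the noise-free limit", {
  m <- population_model("weibull", Te_pop = 40, p_pop = 2.2, sigma = 1)
  t <- seq(2, 40, by = 2)
  data <- data.frame(study_id = "s1", time = t,
                     obs = predict_survival(m, t), n_at_risk = 200)
  data$se <- se_weight(data$obs, data$n_at_risk)
  ft <- fit_tte(data, "weibull", random_effects = FALSE,
                standard_errors = FALSE)
  g <- gof(ft, data)
  expect_gte(g$r_squared, 0.999)
  expect_lt(g$max_abs_residual, 0.01)
  # weighted residuals are standard normal when the data follow the
  # model's own observation equation (i.i.d. scaled Gaussian noise)
  set.seed(91)
  mm <- population_model("weibull", 40, 2.2, omega_Te = 0.2, omega_p = 0.15,
                         sigma = 1)
  rows <- lapply(sprintf("G%02d", 1:10), function(sid) {
    eta <- c(rnorm(1, 0, 0.2), rnorm(1, 0, 0.15))
    tt <- seq(2, 40, by = 1.5)
    pr <- predict_survival(mm, tt, eta = eta)
    se <- se_weight(pr, 250)
    data.frame(study_id = sid, time = tt,
               obs = pmin(0.995, pmax(0.005, pr + rnorm(length(tt)) * se)),
               n_at_risk = 250, se = se)
  })
  data2 <- do.call(rbind, rows)
  ft2 <- fit_tte(data2, "weibull", standard_errors = FALSE)
  g2 <- gof(ft2, data2)
  ks <- stats::ks.test(g2$table$wres / stats::sd(g2$table$wres), "pnorm")
  expect_gt(ks$p.value, 0.01)
})
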