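test_that("binomial SE weights match hand arithmetic and floor rule", {
  expect_equal(se_weight(0.5, 100), 0.05)
  expect_equal(se_weight(0.9, 279), sqrt(0.09 / 279))
  # fractions at the boundary are floored before weighting
  expect_equal(se_weight(0.999, 100), sqrt(0.995 * 0.005 / 100))
  expect_equal(se_weight(0, 50), se_weight(0.005, 50))
})

test_that("the covariate and random-effect chain scales Te multiplicatively", {
  m <- population_model("weibull", Te_pop = 41.69, p_pop = 2.25,
                        theta_cov = c(race_nonasian = 0.19))
  # identity chain reproduces the typical curve
  expect_equal(predict_survival(m, 41.69), exp(-1))
  # covariate multiplies Te by exp(theta): effective Te 41.69*e^0.19 = 50.42
  Te_eff <- 41.69 * exp(0.19)
  expect_equal(predict_survival(m, Te_eff, cov = c(race_nonasian = 1)),
               exp(-1), tolerance = 1e-12)
  # a study effect eta_Te = 0.44 scales Te by e^0.44
  expect_equal(predict_survival(m, 41.69 * exp(0.44), eta = c(0.44, 0)),
               exp(-1), tolerance = 1e-12)
  expect_error(predict_survival(m, 10, cov = c(bogus = 1)), "unknown covariate")
})

test_that("marginal likelihood reduces to the closed form when omega = 0", {
  data <- make_obs_dataset(n_studies = 4, seed = 41)
  m0 <- population_model("weibull", 38, 2.1, sigma = 1.3)
  ll <- marginal_loglik(m0, data)
  pred <- predict_survival(m0, data$time)
  expect_equal(ll, sum(stats::dnorm(data$obs, pred, 1.3 * data$se, log = TRUE)),
               tolerance = 1e-10)
  # single perfect observation: log-density is -log(sigma*SE*sqrt(2pi))
  one <- data.frame(study_id = "s", time = 20,
                    obs = predict_survival(m0, 20), n_at_risk = 100)
  one$se <- se_weight(one$obs, one$n_at_risk)
  m1 <- population_model("weibull", 38, 2.1, sigma = 1)
  expect_equal(marginal_loglik(m1, one), -log(one$se * sqrt(2 * pi)),
               tolerance = 1e-10)
  # doubling sigma changes the log-likelihood by the analytic Gaussian amount
  m2 <- population_model("weibull", 38, 2.1, sigma = 2.6)
  resid2 <- sum((data$obs - pred)^2 / data$se^2)
  expect_equal(marginal_loglik(m2, data) - ll,
               -nrow(data) * log(2) + resid2 / 2 * (1 / 1.3^2 - 1 / 2.6^2) / 1,
               tolerance = 1e-8)
})

test_that("adaptive quadrature agrees with brute-force integration", {
  data <- make_obs_dataset(n_studies = 2, seed = 43, points = 12)
  m <- population_model("weibull", 40, 2.2, omega_Te = 0.3, omega_p = 0.2,
                        sigma = 1)
  llq <- marginal_loglik(m, data)
  grid <- seq(-1.6, 1.6, length.out = 161)
  h <- diff(grid)[1]
  bf <- 0
  for (sid in unique(data$study_id)) {
    d <- data[data$study_id == sid, ]
    dens <- outer(grid, grid, Vectorize(function(a, b) {
      pr <- predict_survival(m, d$time, eta = c(a, b))
      exp(sum(stats::dnorm(d$obs, pr, d$se, log = TRUE))) *
        stats::dnorm(a, 0, 0.3) * stats::dnorm(b, 0, 0.2)
    }))
    bf <- bf + log(sum(dens) * h^2)
  }
  expect_equal(llq, bf, tolerance = 1e-4)
})

test_that("the hierarchical fit recovers generating parameters", {
  data <- make_obs_dataset(n_studies = 10, seed = 47)
  ft <- fit_tte(data, "weibull")
  expect_equal(ft$convergence$code, 0)
  # at 10 studies the estimate tracks the realized study-level means; the
  # residual estimator error is well below the eta-mean sampling noise
  truth <- attr(data, "truth")
  expect_lt(abs(log(ft$model$Te_pop) - (log(40) + mean(truth$eta_Te))), 0.06)
  expect_lt(abs(log(ft$model$p_pop) - (log(2.2) + mean(truth$eta_p))), 0.06)
  expect_true(all(c("Te_pop", "p_pop", "omega_Te", "omega_p", "sigma") %in%
                    ft$estimates$parameter))
  expect_equal(ft$estimates$rse_pct,
               100 * ft$estimates$se / abs(ft$estimates$estimate))
  expect_equal(ft$aic, ft$minus2LL + 2 * ft$k)
  # deterministic: refitting identical data gives an identical result
  ft2 <- fit_tte(data, "weibull")
  expect_identical(ft$estimates, ft2$estimates)
  expect_identical(ft$minus2LL, ft2$minus2LL)
})

test_that("omega estimated near zero when the data carry no study effects", {
  data <- make_obs_dataset(n_studies = 8, seed = 53, omega_Te = 0, omega_p = 0,
                           subjects = c(200, 400))
  ft <- fit_tte(data, "weibull", standard_errors = FALSE)
  expect_lt(ft$model$omega_Te, 0.05)
})

test_that("Wald test matches normal-theory arithmetic", {
  # the published race coefficient: 0.19 with RSE 50% gives z = 2
  w <- wald_test(0.19, 0.19 * 0.50)
  expect_equal(w$z, 2)
  expect_equal(w$p_value, 2 * stats::pnorm(-2), tolerance = 1e-12)
  expect_lt(w$p_value, 0.05)
  expect_equal(wald_test(0, 1)$p_value, 1)
  expect_equal(wald_test(1.96, 1)$p_value, 0.05, tolerance = 1e-3)
  expect_error(wald_test(1, 0), "positive")
})

test_that("AIC bookkeeping and model selection follow the parameter count", {
  data <- make_obs_dataset(n_studies = 6, seed = 59, cov_prop = 0.5)
  covd <- data.frame(study_id = unique(data$study_id))
  set.seed(60)
  covd$x <- stats::runif(nrow(covd))
  f0 <- fit_tte(data, "weibull", standard_errors = FALSE)
  f1 <- fit_tte(data, "weibull", covariates = "x", covariate_data = covd,
                standard_errors = FALSE)
  # adding one covariate adds exactly one counted parameter
  expect_equal(f1$k, f0$k + 1)
  expect_equal(f0$aic, f0$minus2LL + 2 * f0$k)
  # tie rule: identical -2LL prefers fewer parameters
  fa <- f0; fb <- f0
  fb$k <- f0$k + 1; fb$aic <- f0$minus2LL + 2 * fb$k
  expect_identical(select_model(list(fb, fa))$k, f0$k)
  fb$aic <- fa$aic
  expect_identical(select_model(list(fb, fa))$k, f0$k)
  # fits on different data are rejected
  other <- make_obs_dataset(n_studies = 6, seed = 61)
  f2 <- fit_tte(other, "weibull", standard_errors = FALSE)
  expect_error(select_model(list(f0, f2)), "different datasets")
})

test_that("covariate screening keeps a simulated effect and logs the rest", {
  m <- population_model("weibull", 40, 2.2, theta_cov = c(x = 0.3),
                        omega_Te = 0.15, omega_p = 0.15, sigma = 1)
  sp <- trial_spec(12, c(150, 300), m, cov_prop = rep(c(0, 1), 6),
                   admin_cutoff = 40, points_per_curve = 20, seed = 71)
  ipd <- generate_trial(sp)
  set.seed(72)
  curves <- lapply(split(ipd, ipd$study_id), function(d) {
    digitize(d, sp, study_id = d$study_id[1], arm_label = d$study_id[1])
  })
  data <- observation_records(curves)
  covd <- data.frame(study_id = sprintf("S%02d", 1:12),
                     x = rep(c(0, 1), 6))
  sc <- screen_covariates(data, "weibull", "x", covd)
  expect_true(sc$log$kept[sc$log$covariate == "x"])
  expect_lt(sc$log$p_value[1], 0.05)
  expect_equal(names(sc$final$model$theta_cov), "x")
  expect_gt(sc$final$model$theta_cov[["x"]], 0)
})
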