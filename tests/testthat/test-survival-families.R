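test_that("hazards evaluate to their closed forms", {
  # exponential limit of the Weibull at gamma = 1
  expect_equal(tte_hazard(hazard_params("weibull", 1, 1), 5), 1)
  # Gompertz at vanishing gamma is a constant hazard
  expect_equal(tte_hazard(hazard_params("gompertz", 0.1, 1e-12), 7), 0.1,
               tolerance = 1e-9)
  # hand evaluation of the log-logistic hazard
  expect_equal(tte_hazard(hazard_params("loglogistic", 0.5, 2), 2),
               0.5 * 2 * 1 / (1 + 1))
  # diverging hazard at t = 0 for shape < 1 is flagged as Inf
  expect_identical(tte_hazard(hazard_params("weibull", 1, 0.5), 0), Inf)
  expect_error(tte_hazard(hazard_params("weibull", 1, 2), -1), "nonnegative")
  expect_error(tte_hazard(hazard_params("weibull", 1, 2), NaN), "finite")
})

test_that("survival matches the numerically integrated hazard", {
  for (fam in c("weibull", "gompertz", "loglogistic")) {
    for (hp in random_params(fam, 8, seed = 11)) {
      for (t in c(0.5, 2, 10, 35)) {
        num <- exp(-stats::integrate(function(u) tte_hazard(hp, u), 0, t,
                                     rel.tol = 1e-10)$value)
        expect_equal(tte_survival(hp, t), num, tolerance = 1e-6,
                     label = sprintf("%s t=%g", fam, t))
      }
    }
  }
})

test_that("survival honours the natural-parameter convention", {
  expect_equal(tte_survival(hazard_params("weibull", 1, 2), 0), 1)
  # Weibull/Gompertz: S(Te) = exp(-1); log-logistic: S(Te) = 0.5
  expect_equal(tte_survival(natural_params("weibull", 41.69, 2.25), 41.69),
               exp(-1))
  expect_equal(tte_survival(natural_params("gompertz", 20, 0.1), 20), exp(-1))
  expect_equal(tte_survival(natural_params("loglogistic", 27.47, 3.5), 27.47),
               0.5)
  # S nonincreasing, -> 0
  tt <- seq(0, 2000, by = 2)
  for (fam in c("weibull", "gompertz", "loglogistic")) {
    s <- tte_survival(natural_params(fam, 20, 1.5), tt)
    expect_true(all(diff(s) <= 0))
    expect_lt(s[length(s)], 1e-3)   # log-logistic tail is heavy but vanishes
  }
})

test_that("families agree with the standard distribution functions", {
  skip_if_not_installed("flexsurv")
  t <- c(1, 5, 20, 60)
  hp <- hazard_params("weibull", lam = 0.002, gam = 1.8)
  expect_equal(tte_survival(hp, t),
               1 - stats::pweibull(t, shape = 1.8, scale = 0.002^(-1 / 1.8)),
               tolerance = 1e-12)
  hp <- hazard_params("loglogistic", lam = 0.04, gam = 2.5)
  expect_equal(tte_survival(hp, t),
               1 - flexsurv::pllogis(t, shape = 2.5, scale = 1 / 0.04),
               tolerance = 1e-12)
  hp <- hazard_params("gompertz", lam = 0.01, gam = 0.08)
  expect_equal(tte_survival(hp, t),
               1 - flexsurv::pgompertz(t, shape = 0.08, rate = 0.01),
               tolerance = 1e-12)
})

test_that("quantile inverts survival and reproduces published medians", {
  # log-logistic median equals Te; cross-checks the 10.35-month
  # second-line PFS median
  expect_equal(tte_quantile(natural_params("loglogistic", 10.31, 5.92), 0.5),
               10.31)
  # closed-form Weibull median, the 35.41-month Asian first-line OS value
  expect_equal(tte_quantile(natural_params("weibull", 41.69, 2.25), 0.5),
               41.69 * log(2)^(1 / 2.25), tolerance = 1e-10)
  expect_equal(41.69 * log(2)^(1 / 2.25), 35.42, tolerance = 1e-3)
  # q = exp(-1) recovers Te for the cumulative-hazard-1 families
  expect_equal(tte_quantile(natural_params("weibull", 33, 1.7), exp(-1)), 33)
  expect_equal(tte_quantile(natural_params("gompertz", 15, 0.2), exp(-1)), 15,
               tolerance = 1e-10)
  # mutual inverse on a grid, all families
  qs <- c(0.01, 0.1, 0.5, 0.9, 0.99)
  for (fam in c("weibull", "gompertz", "loglogistic")) {
    for (hp in random_params(fam, 5, seed = 23)) {
      expect_equal(tte_survival(hp, tte_quantile(hp, qs)), qs,
                   tolerance = 1e-8)
    }
  }
  expect_error(tte_quantile(natural_params("weibull", 10, 2), 0), "inside")
  expect_error(tte_quantile(natural_params("weibull", 10, 2), 1), "inside")
})

test_that("event-time sampling is deterministic and matches the law", {
  np <- natural_params("weibull", 40, 2)
  set.seed(99); x1 <- tte_sample(np, 10000)
  set.seed(99); x2 <- tte_sample(np, 10000)
  expect_identical(x1, x2)
  expect_equal(stats::median(x1), 40 * log(2)^(1 / 2), tolerance = 0.02)
  # empirical survival at Te within binomial noise of exp(-1)
  emp <- mean(x1 > 40)
  expect_lt(abs(emp - exp(-1)), 3 * sqrt(exp(-1) * (1 - exp(-1)) / 10000))
  set.seed(1)
  one <- tte_sample(np, 1)
  expect_length(one, 1)
  expect_true(is.finite(one) && one > 0)
})

test_that("parameterizations round-trip losslessly", {
  expect_equal(to_natural(hazard_params("weibull", 41.69^-2.25, 2.25))$Te,
               41.69, tolerance = 1e-10)
  expect_equal(to_natural(hazard_params("loglogistic", 1 / 27.47, 3.5))$Te,
               27.47, tolerance = 1e-10)
  for (fam in c("weibull", "gompertz", "loglogistic")) {
    for (hp in random_params(fam, 34, seed = 5)) {
      hp2 <- from_natural(to_natural(hp))
      expect_equal(hp2$lam, hp$lam, tolerance = 1e-10)
      expect_equal(hp2$gam, hp$gam, tolerance = 1e-10)
    }
  }
  expect_error(natural_params("weibull", -1, 2), "positive")
  expect_error(hazard_params("weibull", 1, 0), "positive")
})

test_that("small-shape limits converge to the exponential", {
  t <- c(1, 10, 40)
  expect_equal(tte_survival(hazard_params("weibull", 0.03, 1), t),
               exp(-0.03 * t))
  expect_equal(tte_survival(hazard_params("gompertz", 0.03, 1e-8), t),
               exp(-0.03 * t), tolerance = 1e-6)
})
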