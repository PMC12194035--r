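#' Forward-simulation scenario
#'
#' Defines a Monte Carlo extrapolation of a fitted (or published) population
#' model: per replicate one set of study-level effects is drawn from
#' \eqn{N(0, \omega^2)}, each subject's covariate stratum is drawn from the
#' mix, and event times are sampled by inverse-CDF; replicate KM medians and
#' landmark rates are summarized across replicates.
#'
#' @param model A [population_model()].
#' @param covariate_mix Data frame with a `weight` column (summing to 1) and
#'   one column per covariate named in `model$theta_cov`; NULL for a single
#'   reference stratum.
#' @param n_replicates Number of replicates (default 1000).
#' @param subjects_per_replicate Cohort size per replicate (default 279, a
#'   typical trial-arm size).
#' @param landmark_times Months at which survival rates are reported.
#' @param time_grid Grid for percentile bands (default 0..72 by 1 month).
#' @param seed Master seed; per-replicate child seeds are derived from it.
#' @return Object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(model, covariate_mix = NULL,
                                n_replicates = 1000,
                                subjects_per_replicate = 279,
                                landmark_times = c(12, 36, 60),
                                time_grid = seq(0, 72, by = 1),
                                seed = 1) {
  stopifnot(inherits(model, "population_model"),
            n_replicates >= 1, subjects_per_replicate >= 1)
  if (is.null(covariate_mix)) {
    covariate_mix <- data.frame(weight = 1)
    for (nm in names(model$theta_cov)) covariate_mix[[nm]] <- 0
  }
  stopifnot("weight" %in% names(covariate_mix),
            abs(sum(covariate_mix$weight) - 1) < 1e-8)
  structure(list(model = model, covariate_mix = covariate_mix,
                 n_replicates = as.integer(n_replicates),
                 subjects_per_replicate = as.integer(subjects_per_replicate),
                 landmark_times = landmark_times, time_grid = time_grid,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

stratum_params <- function(model, mix_row) {
  shift <- 0
  for (nm in names(model$theta_cov)) shift <- shift + model$theta_cov[[nm]] * mix_row[[nm]]
  shift
}

#' Run a simulation scenario
#'
#' Per replicate: draw \eqn{\eta_{Te}, \eta_p}, assign covariate strata to
#' subjects, sample event times and compute the replicate KM median and
#' landmark survival rates. The median point estimate is the median of
#' replicate medians with a 2.5-97.5 percentile CI; landmark rates are
#' pooled trajectory means with percentile CIs; percentile bands give the
#' 10th/50th/90th percentiles of the replicate survival curves on the time
#' grid. Replicates whose KM never crosses 0.5 within the grid are excluded
#' from the median distribution and counted (with a warning above 5%).
#'
#' @param scn A [simulation_scenario()].
#' @return Object of class `simulation_summary` with elements `median`
#'   (point, lower, upper, n_excluded), `landmark_rates` (data frame),
#'   `percentile_bands` (data frame) and the scenario.
#' @export
simulate_scenario <- function(scn) {
  stopifnot(inherits(scn, "simulation_scenario"))
  m <- scn$model
  mix <- scn$covariate_mix
  R <- scn$n_replicates; n <- scn$subjects_per_replicate
  set.seed(scn$seed)
  child <- sample.int(.Machine$integer.max - 1L, R)
  shifts <- vapply(seq_len(nrow(mix)), function(s) stratum_params(m, mix[s, , drop = FALSE]),
                   numeric(1))
  meds <- rep(NA_real_, R)
  lmk <- matrix(NA_real_, R, length(scn$landmark_times))
  bands <- matrix(NA_real_, R, length(scn$time_grid))
  for (r in seq_len(R)) {
    set.seed(child[r])
    eta_Te <- stats::rnorm(1, 0, m$omega_Te)
    eta_p <- stats::rnorm(1, 0, m$omega_p)
    strat <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
    u <- stats::runif(n)
    tt <- numeric(n)
    for (s in unique(strat)) {
      np <- natural_params(m$family,
                           Te = m$Te_pop * exp(shifts[s] + eta_Te),
                           p = m$p_pop * exp(eta_p))
      tt[strat == s] <- tte_quantile(np, u[strat == s])
    }
    st <- sort(tt)
    meds[r] <- st[ceiling(n / 2)]             # KM median; always defined
                                              # when no replicate censoring
    lmk[r, ] <- vapply(scn$landmark_times, function(tl) mean(tt > tl), numeric(1))
    bands[r, ] <- vapply(scn$time_grid, function(tg) mean(tt > tg), numeric(1))
  }
  n_excluded <- sum(is.na(meds))
  if (n_excluded > 0.05 * R) {
    warning(sprintf("%d/%d replicates never crossed S = 0.5 within the grid",
                    n_excluded, R))
  }
  med_ok <- meds[!is.na(meds)]
  landmark <- data.frame(
    time = scn$landmark_times,
    rate = colMeans(lmk),
    lower = apply(lmk, 2, stats::quantile, 0.025),
    upper = apply(lmk, 2, stats::quantile, 0.975))
  pb <- data.frame(
    time = scn$time_grid,
    p10 = apply(bands, 2, stats::quantile, 0.10),
    p50 = apply(bands, 2, stats::quantile, 0.50),
    p90 = apply(bands, 2, stats::quantile, 0.90))
  structure(list(
    median = list(point = stats::median(med_ok),
                  lower = unname(stats::quantile(med_ok, 0.025)),
                  upper = unname(stats::quantile(med_ok, 0.975)),
                  n_excluded = n_excluded),
    landmark_rates = landmark,
    percentile_bands = pb,
    scenario = scn), class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("<simulation: %d replicates x %d subjects, %s model>\n",
              x$scenario$n_replicates, x$scenario$subjects_per_replicate,
              x$scenario$model$family))
  cat(sprintf("median survival %.2f months (95%% CI %.2f-%.2f)%s\n",
              x$median$point, x$median$lower, x$median$upper,
              if (x$median$n_excluded) sprintf(" [%d replicates excluded]", x$median$n_excluded) else ""))
  for (i in seq_len(nrow(x$landmark_rates))) {
    cat(sprintf("  S(%g mo) = %.1f%% (%.1f-%.1f)\n", x$landmark_rates$time[i],
                100 * x$landmark_rates$rate[i], 100 * x$landmark_rates$lower[i],
                100 * x$landmark_rates$upper[i]))
  }
  invisible(x)
}

#' Random-effect-averaged landmark survival rate
#'
#' Mixture-weighted survival probability at horizon `t`, averaged over the
#' study-level random effects either by 2-D Gauss-Hermite quadrature
#' (deterministic, default) or Monte Carlo. With `with_random_effects =
#' FALSE` the typical-curve survival is returned, and the mixture rate is
#' then exactly the weighted average of stratum rates.
#'
#' @param model A [population_model()].
#' @param covariate_mix As in [simulation_scenario()].
#' @param t Horizon(s), months.
#' @param with_random_effects Average over \eqn{\eta} (TRUE) or evaluate at
#'   \eqn{\eta = 0}.
#' @param method `"quadrature"` or `"mc"`.
#' @param n_draws Monte Carlo draws when `method = "mc"`.
#' @param quad_nodes Gauss-Hermite nodes per dimension.
#' @param seed Seed for the MC path.
#' @return Numeric vector of rates, one per element of `t`.
#' @export
landmark_rate <- function(model, covariate_mix = NULL, t,
                          with_random_effects = TRUE,
                          method = c("quadrature", "mc"),
                          n_draws = 10000, quad_nodes = 21, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(model, "population_model"), all(t >= 0))
  if (is.null(covariate_mix)) {
    covariate_mix <- data.frame(weight = 1)
    for (nm in names(model$theta_cov)) covariate_mix[[nm]] <- 0
  }
  shifts <- vapply(seq_len(nrow(covariate_mix)),
                   function(s) stratum_params(model, covariate_mix[s, , drop = FALSE]),
                   numeric(1))
  w <- covariate_mix$weight
  if (!with_random_effects || (model$omega_Te == 0 && model$omega_p == 0)) {
    eta <- matrix(0, 1, 2); ew <- 1
  } else if (method == "quadrature") {
    gh <- pracma::gaussHermite(quad_nodes)
    g <- expand.grid(a = seq_len(quad_nodes), b = seq_len(quad_nodes))
    eta <- cbind(sqrt(2) * model$omega_Te * gh$x[g$a],
                 sqrt(2) * model$omega_p * gh$x[g$b])
    ew <- gh$w[g$a] * gh$w[g$b] / pi
  } else {
    set.seed(seed)
    eta <- cbind(stats::rnorm(n_draws, 0, model$omega_Te),
                 stats::rnorm(n_draws, 0, model$omega_p))
    ew <- rep(1 / n_draws, n_draws)
  }
  vapply(t, function(tl) {
    if (tl == 0) return(1)
    tot <- 0
    for (s in seq_along(shifts)) {
      Te <- model$Te_pop * exp(shifts[s] + eta[, 1])
      p <- model$p_pop * exp(eta[, 2])
      H <- cumhaz_matrix(model$family, Te, p, tl)
      tot <- tot + w[s] * sum(ew * exp(-drop(H)))
    }
    tot
  }, numeric(1))
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the observed design (same
#' studies, observation times and SE weights; study effects redrawn from the
#' fitted \eqn{\omega}, residuals from the fitted \eqn{\sigma}) and compares
#' the observed fractions with the simulated 10th/50th/90th percentile
#' bands, reporting the fraction of observations inside the 10-90 band.
#'
#' @param fit A `tte_fit` (or a [population_model()]).
#' @param data The observation table the model was fitted to.
#' @param covariate_data Study-level covariates, as in [fit_tte()].
#' @param n_sim Number of simulated replicate datasets.
#' @param seed Seed.
#' @return Object of class `vpc_report`: per-observation table (`study_id`,
#'   `time`, `obs`, `q10`, `q50`, `q90`, `in_band`) plus `frac_in_band`.
#' @export
vpc <- function(fit, data, covariate_data = NULL, n_sim = 200, seed = 1) {
  model <- if (inherits(fit, "tte_fit")) fit$model else fit
  stopifnot(inherits(model, "population_model"))
  sdl <- prep_study_data(data, covariate_data, names(model$theta_cov))
  set.seed(seed)
  rows <- vector("list", length(sdl))
  for (j in seq_along(sdl)) {
    sd_ <- sdl[[j]]
    eta_Te <- stats::rnorm(n_sim, 0, model$omega_Te)
    eta_p <- stats::rnorm(n_sim, 0, model$omega_p)
    shift <- if (length(model$theta_cov)) sum(unlist(model$theta_cov) * sd_$cov) else 0
    Te <- model$Te_pop * exp(shift + eta_Te)
    p <- model$p_pop * exp(eta_p)
    H <- cumhaz_matrix(model$family, Te, p, sd_$t)   # J x n_sim
    pred <- exp(-H)
    eps <- matrix(stats::rnorm(length(pred), 0, model$sigma), nrow(pred))
    ysim <- pred + eps * sd_$se
    q <- apply(ysim, 1, stats::quantile, c(0.10, 0.50, 0.90))
    rows[[j]] <- data.frame(study_id = sd_$study_id, time = sd_$t,
                            obs = sd_$obs, q10 = q[1, ], q50 = q[2, ],
                            q90 = q[3, ])
  }
  tab <- do.call(rbind, rows)
  tab$in_band <- tab$obs >= tab$q10 & tab$obs <= tab$q90
  structure(list(table = tab, frac_in_band = mean(tab$in_band),
                 n_sim = n_sim), class = "vpc_report")
}

#' @export
print.vpc_report <- function(x, ...) {
  cat(sprintf("<VPC: %d simulated datasets, %.1f%% of %d observations inside the 10-90 band>\n",
              x$n_sim, 100 * x$frac_in_band, nrow(x$table)))
  invisible(x)
}

#' @export
plot.vpc_report <- function(x, ...) {
  tab <- x$table[order(x$table$time), ]
  graphics::plot(tab$time, tab$obs, pch = 16, cex = 0.6,
                 xlab = "time (months)", ylab = "survival fraction",
                 ylim = c(0, 1), ...)
  graphics::lines(tab$time, tab$q50, col = "steelblue", lwd = 2)
  graphics::lines(tab$time, tab$q10, col = "steelblue", lty = 2)
  graphics::lines(tab$time, tab$q90, col = "steelblue", lty = 2)
  invisible(x)
}

#' @export
plot.simulation_summary <- function(x, ...) {
  pb <- x$percentile_bands
  graphics::plot(pb$time, pb$p50, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "time (months)", ylab = "survival", ...)
  graphics::lines(pb$time, pb$p10, lty = 2)
  graphics::lines(pb$time, pb$p90, lty = 2)
  invisible(x)
}

#' Goodness-of-fit table
#'
#' Pairs each observation with its population prediction (\eqn{\eta = 0})
#' and study-level prediction (empirical-Bayes \eqn{\hat\eta}), and reports
#' the coefficient of determination of the study-level predictions, the
#' maximum absolute residual, and the weighted residuals
#' \eqn{(obs - pred)/(\hat\sigma SE)}.
#'
#' @param fit A `tte_fit`.
#' @param data The observation table the model was fitted to.
#' @param covariate_data Study-level covariates.
#' @return List with `table`, `r_squared`, `max_abs_residual`.
#' @export
gof <- function(fit, data, covariate_data = NULL) {
  stopifnot(inherits(fit, "tte_fit"))
  model <- fit$model
  sdl <- prep_study_data(data, covariate_data, names(model$theta_cov))
  eff <- fit$study_effects
  rows <- lapply(sdl, function(sd_) {
    e <- eff[eff$study_id == sd_$study_id, ]
    eta <- if (nrow(e)) c(e$eta_Te[1], e$eta_p[1]) else c(0, 0)
    shift <- if (length(model$theta_cov)) sum(unlist(model$theta_cov) * sd_$cov) else 0
    pred_pop <- exp(-drop(cumhaz_matrix(model$family,
                                        model$Te_pop * exp(shift),
                                        model$p_pop, sd_$t)))
    pred_ind <- exp(-drop(cumhaz_matrix(model$family,
                                        model$Te_pop * exp(shift + eta[1]),
                                        model$p_pop * exp(eta[2]), sd_$t)))
    data.frame(study_id = sd_$study_id, time = sd_$t, obs = sd_$obs,
               pred_pop = pred_pop, pred_ind = pred_ind,
               resid = sd_$obs - pred_ind,
               wres = (sd_$obs - pred_ind) / (model$sigma * sd_$se))
  })
  tab <- do.call(rbind, rows)
  r2 <- 1 - sum(tab$resid^2) / sum((tab$obs - mean(tab$obs))^2)
  list(table = tab, r_squared = r2, max_abs_residual = max(abs(tab$resid)))
}
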