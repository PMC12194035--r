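#' Population time-to-event model
#'
#' The hierarchical model for multi-study survival fractions. Study `i`'s
#' natural parameters are
#' \deqn{T_{e,i} = T_{e,pop} \cdot e^{\theta_{cov} COV_i} \cdot e^{\eta_{Te,i}},
#'   \qquad p_i = p_{pop} \cdot e^{\eta_{p,i}},}
#' with independent study-level effects \eqn{\eta \sim N(0, \omega^2)}.
#' Observed survival fractions are modelled as
#' \eqn{Obs_{ij} = Pred_{ij} + \epsilon_{ij} SE_{ij}} with
#' \eqn{\epsilon \sim N(0, \sigma^2)} and \eqn{SE_{ij} =
#' \sqrt{Obs_{ij}(1 - Obs_{ij}) / N_{ij}}} the binomial standard error at the
#' number at risk \eqn{N_{ij}}.
#'
#' @param family `"weibull"`, `"gompertz"` or `"loglogistic"`.
#' @param Te_pop,p_pop Typical natural parameters (months, dimensionless).
#' @param theta_cov Named list/vector of covariate coefficients acting on
#'   `Te` (e.g. `c(race_nonasian = 0.19)`).
#' @param omega_Te,omega_p Standard deviations of the study-level random
#'   effects on log Te and log p.
#' @param sigma Residual scale multiplying the binomial SE.
#' @return An object of class `population_model`.
#' @export
population_model <- function(family, Te_pop, p_pop, theta_cov = NULL,
                             omega_Te = 0, omega_p = 0, sigma = 1) {
  family <- match_family(family)
  stopifnot(Te_pop > 0, p_pop > 0, omega_Te >= 0, omega_p >= 0, sigma >= 0)
  theta_cov <- if (is.null(theta_cov)) numeric(0) else unlist(theta_cov)
  if (length(theta_cov) && is.null(names(theta_cov))) {
    stop("`theta_cov` must be named by covariate")
  }
  structure(list(family = family, Te_pop = Te_pop, p_pop = p_pop,
                 theta_cov = theta_cov, omega_Te = omega_Te,
                 omega_p = omega_p, sigma = sigma),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<%s population model: Te_pop = %.4g mo, p_pop = %.4g, omega = (%.3g, %.3g), sigma = %.3g>\n",
              x$family, x$Te_pop, x$p_pop, x$omega_Te, x$omega_p, x$sigma))
  if (length(x$theta_cov)) {
    cat("  covariates on Te:",
        paste(sprintf("%s = %.4g", names(x$theta_cov), x$theta_cov), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Published osimertinib population models
#'
#' Final (and base) population time-to-event parameter sets reported for
#' osimertinib meta-analyses of first-/second-line overall and
#' progression-free survival in EGFR-mutated NSCLC: Weibull with a race
#' covariate on Te for first-line OS; log-logistic for second-line OS and
#' both PFS endpoints. The race covariate is coded 1 for the non-Asian
#' stratum (Asian reference). These support simulation-only analyses when
#' the original digitized curves are not at hand.
#'
#' @return Named list of [population_model()] objects.
#' @export
reference_models <- function() {
  list(
    os_first_line_base = population_model(
      "weibull", Te_pop = 44.31, p_pop = 2.56,
      omega_Te = 0.58, omega_p = 0.54),
    os_first_line_final = population_model(
      "weibull", Te_pop = 41.69, p_pop = 2.25,
      theta_cov = c(race_nonasian = 0.19),
      omega_Te = 0.44, omega_p = 0.54),
    os_second_line_base = population_model(
      "loglogistic", Te_pop = 27.47, p_pop = 3.5,
      omega_Te = 0.6, omega_p = 0.75),
    pfs_first_line_final = population_model(
      "loglogistic", Te_pop = 18.03, p_pop = 5.88,
      omega_Te = 0.8, omega_p = 0.81),
    pfs_second_line_final = population_model(
      "loglogistic", Te_pop = 10.31, p_pop = 5.92,
      omega_Te = 0.93, omega_p = 0.74)
  )
}

#' Binomial standard-error weight for an observed survival fraction
#'
#' \eqn{SE = \sqrt{obs (1 - obs) / n}} with the observation first floored to
#' the interval \[0.005, 0.995\] so fractions of 0 or 1 never produce a zero
#' weight.
#'
#' @param obs Observed survival probability.
#' @param n_at_risk Number at risk at the observation time.
#' @export
se_weight <- function(obs, n_at_risk) {
  stopifnot(all(n_at_risk >= 1))
  obs <- pmin(0.995, pmax(0.005, obs))
  sqrt(obs * (1 - obs) / n_at_risk)
}

#' Build observation records from digitized curves
#'
#' Flattens one or more digitized curves into the observation table the
#' hierarchical fit consumes: one row per (study, time point) with the
#' observed survival fraction, the number at risk linearly interpolated from
#' the risk table (floored at 1), and the binomial SE weight. The
#' deterministic origin (time 0) is dropped; fractions are floored to
#' \[0.005, 0.995\].
#'
#' @param curves A [digitized_curve()] or list of them.
#' @return Data frame with columns `study_id`, `time`, `obs`, `n_at_risk`,
#'   `se`.
#' @export
observation_records <- function(curves) {
  if (inherits(curves, "digitized_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    pts <- cv$points[cv$points$time > 0, , drop = FALSE]
    rt <- cv$risk_table
    n_interp <- stats::approx(rt$time, rt$n_at_risk, xout = pts$time,
                              rule = 2)$y
    n_interp <- pmax(1, n_interp)
    obs <- pmin(0.995, pmax(0.005, pts$surv))
    data.frame(study_id = cv$study_id, time = pts$time, obs = obs,
               n_at_risk = n_interp, se = se_weight(obs, n_interp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict the survival fraction for one study
#'
#' Applies the covariate and random-effect chain to the typical parameters
#' and evaluates the closed-form survival.
#'
#' @param model A [population_model()].
#' @param t Times (months).
#' @param eta Length-2 numeric `c(eta_Te, eta_p)` study-level effects.
#' @param cov Named numeric vector of covariate values for the study; names
#'   must match `model$theta_cov` (missing covariates default to 0).
#' @export
predict_survival <- function(model, t, eta = c(0, 0), cov = NULL) {
  stopifnot(inherits(model, "population_model"), length(eta) == 2L)
  shift <- 0
  if (length(model$theta_cov)) {
    nm <- names(model$theta_cov)
    if (!is.null(cov)) {
      unknown <- setdiff(names(cov), nm)
      if (length(unknown)) stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
    }
    vals <- vapply(nm, function(x) if (!is.null(cov) && x %in% names(cov)) cov[[x]] else 0,
                   numeric(1))
    shift <- sum(model$theta_cov * vals)
  } else if (!is.null(cov) && length(cov)) {
    stop("model has no covariate coefficients but `cov` was supplied")
  }
  np <- natural_params(model$family,
                       Te = model$Te_pop * exp(shift + eta[1]),
                       p = model$p_pop * exp(eta[2]))
  tte_survival(np, t)
}

# ---- internal likelihood machinery ----------------------------------------

# Cumulative hazard for vectors of natural parameters (length M) at times t
# (length J); returns a J x M matrix. Times must be positive.
cumhaz_matrix <- function(family, Te, p, t) {
  J <- length(t); M <- length(Te)
  switch(family,
    weibull = {
      L <- outer(log(t), log(Te), "-")          # log(t/Te)
      exp(L * rep(p, each = J))
    },
    loglogistic = {
      L <- outer(log(t), log(Te), "-")
      log1p(exp(L * rep(p, each = J)))
    },
    gompertz = {
      lam_over_gam <- 1 / expm1(p * Te)         # (lam/gam) with lam = gam/expm1(gam Te)
      expm1(outer(t, p)) * rep(lam_over_gam, each = J)
    }
  )
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Per-study data prepared once per likelihood call
prep_study_data <- function(data, covariate_data, theta_names) {
  sids <- unique(data$study_id)
  lapply(sids, function(sid) {
    d <- data[data$study_id == sid, , drop = FALSE]
    covs <- stats::setNames(numeric(length(theta_names)), theta_names)
    if (length(theta_names)) {
      if (is.null(covariate_data)) stop("covariate data required for covariate model")
      row <- covariate_data[covariate_data$study_id == sid, , drop = FALSE]
      if (nrow(row) != 1L) stop("missing covariate row for study ", sid)
      for (nm in theta_names) {
        if (!nm %in% names(row)) stop("unknown covariate name: ", nm)
        covs[nm] <- row[[nm]]
      }
    }
    list(study_id = sid, t = d$time, obs = d$obs, se = d$se, cov = covs)
  })
}

# Conditional negative log joint density of one study's observations and
# random effects, vectorized over an M-column matrix eta (2 x M).
cond_neglogjoint <- function(sd_, family, logTe_typ, logp_typ, theta, sigma,
                             omega, eta) {
  M <- ncol(eta)
  shift <- if (length(theta)) sum(theta * sd_$cov) else 0
  Te <- exp(logTe_typ + shift + eta[1, ])
  p <- exp(logp_typ + eta[2, ])
  H <- cumhaz_matrix(family, Te, p, sd_$t)
  pred <- exp(-H)
  sd_vec <- sigma * sd_$se
  rss <- colSums((sd_$obs - pred)^2 / sd_vec^2) / 2
  const <- sum(log(sd_vec)) + length(sd_$t) * log(2 * pi) / 2
  pen <- numeric(M)
  for (k in 1:2) {
    if (omega[k] > 0) {
      pen <- pen + eta[k, ]^2 / (2 * omega[k]^2) + log(omega[k]) + log(2 * pi) / 2
    }
  }
  rss + const + pen
}

# Cumulative hazard plus its derivatives w.r.t. the log-scale shifts
# eta_Te and eta_p, for scalar (Te, p) at a vector of times.
cumhaz_grad <- function(family, Te, p, t) {
  switch(family,
    weibull = {
      H <- exp(p * (log(t) - log(Te)))
      list(H = H, dTe = -p * H, dp = H * log(pmax(H, 1e-300)))
    },
    loglogistic = {
      X <- exp(p * (log(t) - log(Te)))
      list(H = log1p(X), dTe = -p * X / (1 + X),
           dp = X * log(pmax(X, 1e-300)) / (1 + X))
    },
    gompertz = {
      den <- expm1(p * Te)
      H <- expm1(p * t) / den
      dTe <- -H * p * Te * exp(p * Te) / den
      dp_raw <- (t * exp(p * t) * den - expm1(p * t) * Te * exp(p * Te)) / den^2
      list(H = H, dTe = dTe, dp = p * dp_raw)
    }
  )
}

# Long-vector batch representation of the observation table: one pass over
# all studies per likelihood evaluation.
prep_batch <- function(data, covariate_data, theta_names) {
  sids <- unique(data$study_id)
  idx <- match(data$study_id, sids)
  S <- length(sids)
  k <- length(theta_names)
  covmat <- matrix(0, S, k)
  if (k) {
    if (is.null(covariate_data)) stop("covariate data required for covariate model")
    for (j in seq_len(S)) {
      row <- covariate_data[covariate_data$study_id == sids[j], , drop = FALSE]
      if (nrow(row) != 1L) stop("missing covariate row for study ", sids[j])
      for (a in seq_len(k)) {
        if (!theta_names[a] %in% names(row)) {
          stop("unknown covariate name: ", theta_names[a])
        }
        covmat[j, a] <- row[[theta_names[a]]]
      }
    }
  }
  list(t = data$time, obs = data$obs, se = data$se, idx = idx,
       study_ids = sids, covmat = covmat, S = S,
       n_s = drop(rowsum(rep(1, length(idx)), idx)))
}

# Per-study negative log joint density (and Gauss-Newton curvature) at a
# matrix of random effects eta (S x 2), all studies in one vectorized pass.
eval_batch <- function(family, logTe, logp, theta, sigma, omega, b, eta,
                       derivs = TRUE) {
  shift_s <- if (length(theta)) drop(b$covmat %*% theta) else rep(0, b$S)
  Te_s <- exp(logTe + shift_s + eta[, 1])
  p_s <- exp(logp + eta[, 2])
  g <- cumhaz_grad(family, Te_s[b$idx], p_s[b$idx], b$t)
  pred <- exp(-g$H)
  w2 <- (sigma * b$se)^2
  r <- pred - b$obs
  f_s <- drop(rowsum(r^2 / w2, b$idx)) / 2 +
    drop(rowsum(log(sigma * b$se), b$idx)) + b$n_s * log(2 * pi) / 2
  for (kk in 1:2) {
    if (omega[kk] > 0) {
      f_s <- f_s + eta[, kk]^2 / (2 * omega[kk]^2) + log(omega[kk]) + log(2 * pi) / 2
    }
  }
  out <- list(f = f_s)
  if (derivs) {
    d1 <- -pred * g$dTe
    d2 <- -pred * g$dp
    out$g1 <- drop(rowsum(d1 * r / w2, b$idx)) +
      (if (omega[1] > 0) eta[, 1] / omega[1]^2 else 0)
    out$g2 <- drop(rowsum(d2 * r / w2, b$idx)) +
      (if (omega[2] > 0) eta[, 2] / omega[2]^2 else 0)
    out$H11 <- drop(rowsum(d1^2 / w2, b$idx)) +
      (if (omega[1] > 0) 1 / omega[1]^2 else 0)
    out$H22 <- drop(rowsum(d2^2 / w2, b$idx)) +
      (if (omega[2] > 0) 1 / omega[2]^2 else 0)
    out$H12 <- drop(rowsum(d1 * d2 / w2, b$idx))
  }
  out
}

# Vectorized damped Newton for all studies' posterior modes at once:
# analytic gradient, Gauss-Newton Hessian (exact prior curvature).
batch_modes <- function(family, logTe, logp, theta, sigma, omega, b, free,
                        start) {
  eta <- start
  ev <- eval_batch(family, logTe, logp, theta, sigma, omega, b, eta)
  for (it in 1:40) {
    if (length(free) == 2L) {
      det <- ev$H11 * ev$H22 - ev$H12^2
      det <- pmax(det, 1e-12)
      s1 <- (ev$H22 * ev$g1 - ev$H12 * ev$g2) / det
      s2 <- (ev$H11 * ev$g2 - ev$H12 * ev$g1) / det
      gmax <- max(abs(ev$g1), abs(ev$g2))
    } else if (free == 1L) {
      s1 <- ev$g1 / pmax(ev$H11, 1e-12); s2 <- 0
      gmax <- max(abs(ev$g1))
    } else {
      s1 <- 0; s2 <- ev$g2 / pmax(ev$H22, 1e-12)
      gmax <- max(abs(ev$g2))
    }
    if (gmax < 1e-9) break
    lambda <- rep(1, b$S)
    for (ls in 1:12) {
      eta_try <- eta
      if (1L %in% free) eta_try[, 1] <- eta[, 1] - lambda * s1
      if (2L %in% free) eta_try[, 2] <- eta[, 2] - lambda * s2
      ev_try <- eval_batch(family, logTe, logp, theta, sigma, omega, b, eta_try)
      bad <- !is.finite(ev_try$f) | ev_try$f > ev$f + 1e-12
      if (!any(bad)) break
      lambda[bad] <- lambda[bad] / 2
    }
    if (any(bad)) {                           # stuck studies stay put
      eta_try[bad, ] <- eta[bad, ]
      for (nm in names(ev_try)) ev_try[[nm]][bad] <- ev[[nm]][bad]
    }
    moved <- max(abs(eta_try - eta))
    eta <- eta_try; ev <- ev_try
    if (moved < 1e-10) break
  }
  list(eta = eta, ev = ev)
}

# Adaptive Gauss-Hermite marginal log-likelihood, one value per study.
batch_marginal_ll <- function(family, logTe, logp, theta, sigma, omega, b,
                              gh, cache_env) {
  free <- which(omega > 0)
  if (length(free) == 0L) {
    ev <- eval_batch(family, logTe, logp, theta, sigma, omega, b,
                     matrix(0, b$S, 2), derivs = FALSE)
    return(list(ll = -ev$f, eta = matrix(0, b$S, 2)))
  }
  start <- cache_env$eta
  if (is.null(start) || nrow(start) != b$S) start <- matrix(0, b$S, 2)
  bm <- batch_modes(family, logTe, logp, theta, sigma, omega, b, free, start)
  cache_env$eta <- bm$eta
  ev <- bm$ev
  d <- length(free)
  if (d == 2L) {
    det <- pmax(ev$H11 * ev$H22 - ev$H12^2, 1e-12)
    S11 <- ev$H22 / det; S22 <- ev$H11 / det; S12 <- -ev$H12 / det
    a11 <- sqrt(pmax(S11, 1e-300))
    a12 <- S12 / a11
    a22 <- sqrt(pmax(S22 - a12^2, 1e-300))
    gx <- expand.grid(x1 = gh$x, x2 = gh$x)
    logw <- log(expand.grid(w1 = gh$w, w2 = gh$w))
    logw <- logw$w1 + logw$w2 + gx$x1^2 + gx$x2^2
    M <- nrow(gx)
    eta1 <- bm$eta[, 1] + sqrt(2) * outer(a11, gx$x1)
    eta2 <- bm$eta[, 2] + sqrt(2) * (outer(a12, gx$x1) + outer(a22, gx$x2))
    log_det_A <- log(a11) + log(a22)
  } else {
    Hd <- if (free == 1L) ev$H11 else ev$H22
    a <- sqrt(1 / pmax(Hd, 1e-12))
    M <- length(gh$x)
    logw <- log(gh$w) + gh$x^2
    nd <- sqrt(2) * outer(a, gh$x)
    if (free == 1L) {
      eta1 <- bm$eta[, 1] + nd; eta2 <- matrix(bm$eta[, 2], b$S, M)
    } else {
      eta2 <- bm$eta[, 2] + nd; eta1 <- matrix(bm$eta[, 1], b$S, M)
    }
    log_det_A <- log(a)
  }
  # f at all (study, node) pairs in one pass over an n_obs x M expansion
  shift_s <- if (length(theta)) drop(b$covmat %*% theta) else rep(0, b$S)
  lTe <- logTe + shift_s + eta1                   # S x M
  lp <- logp + eta2
  Te_mat <- exp(lTe[b$idx, , drop = FALSE])
  p_mat <- exp(lp[b$idx, , drop = FALSE])
  H <- cumhaz_only(family, Te_mat, p_mat, b$t)
  pred <- exp(-H)
  w2 <- (sigma * b$se)^2
  rss <- rowsum((pred - b$obs)^2 / w2, b$idx) / 2   # S x M
  f_sn <- rss + drop(rowsum(log(sigma * b$se), b$idx)) + b$n_s * log(2 * pi) / 2
  for (kk in free) {
    em <- if (kk == 1L) eta1 else eta2
    f_sn <- f_sn + em^2 / (2 * omega[kk]^2) + log(omega[kk]) + log(2 * pi) / 2
  }
  expo <- sweep(-f_sn, 2, logw, "+")
  mx <- apply(expo, 1, max)
  ll <- mx + log(rowSums(exp(expo - mx))) + d / 2 * log(2) + log_det_A
  list(ll = ll, eta = bm$eta)
}

# Cumulative hazard for elementwise matrices/vectors of (Te, p) and a time
# vector recycled down rows.
cumhaz_only <- function(family, Te, p, t) {
  switch(family,
    weibull = exp(p * (log(t) - log(Te))),
    loglogistic = log1p(exp(p * (log(t) - log(Te)))),
    gompertz = expm1(p * t) / expm1(p * Te)
  )
}

#' Marginal log-likelihood of the hierarchical curve model
#'
#' Integrates each study's Gaussian observation density over the study-level
#' random effects \eqn{(\eta_{Te}, \eta_p) \sim N(0, diag(\omega^2))} by
#' adaptive Gauss-Hermite quadrature (nodes recentred at the posterior mode
#' and rescaled by the local curvature; default 9 nodes per free dimension).
#' With all \eqn{\omega = 0} this reduces exactly to the closed-form weighted
#' Gaussian log-likelihood of the typical curve.
#'
#' @param model A [population_model()].
#' @param data Observation table from [observation_records()].
#' @param covariate_data Optional data frame, one row per study, column
#'   `study_id` plus one column per covariate named in `model$theta_cov`.
#' @param quad_nodes Gauss-Hermite nodes per dimension (>= 9 recommended).
#' @return Log-likelihood (finite, or `-Inf` with a warning when a study's
#'   contribution underflows).
#' @export
marginal_loglik <- function(model, data, covariate_data = NULL, quad_nodes = 9) {
  stopifnot(inherits(model, "population_model"))
  b <- prep_batch(data, covariate_data, names(model$theta_cov))
  gh <- pracma::gaussHermite(quad_nodes)
  cache <- new.env(parent = emptyenv())
  res <- batch_marginal_ll(model$family, log(model$Te_pop), log(model$p_pop),
                           model$theta_cov, model$sigma,
                           c(model$omega_Te, model$omega_p), b, gh, cache)
  if (any(!is.finite(res$ll))) {
    warning("non-finite likelihood contribution for study(ies): ",
            paste(b$study_ids[!is.finite(res$ll)], collapse = ", "))
  }
  sum(res$ll)
}

# ---- fitting ---------------------------------------------------------------

start_values <- function(family, data) {
  # typical-curve weighted least squares on the pooled fractions
  obj <- function(par) {
    H <- cumhaz_matrix(family, exp(par[1]), exp(par[2]), data$time)
    sum((data$obs - exp(-H))^2 / data$se^2)
  }
  # crude Te start: time at which the pooled curve crosses its defining level
  lev <- if (family == "loglogistic") 0.5 else exp(-1)
  Te0 <- data$time[which.min(abs(data$obs - lev))]
  if (!length(Te0) || Te0 <= 0) Te0 <- stats::median(data$time)
  opt <- stats::optim(c(log(Te0), log(2)), obj, method = "Nelder-Mead",
                      control = list(maxit = 300))
  opt$par
}

#' Fit the hierarchical parametric survival-fraction model
#'
#' Maximizes the quadrature-marginalized likelihood over the typical
#' parameters (log scale), covariate coefficients, random-effect SDs and
#' residual scale (log scales) with `nlminb`. Standard errors come from the
#' inverse finite-difference Hessian of the negative marginal log-likelihood,
#' delta-transformed to the natural scale; study-level effects are returned
#' as empirical-Bayes posterior modes. Fits are deterministic for fixed data.
#'
#' @param data Observation table from [observation_records()].
#' @param family Hazard family to fit.
#' @param covariates Character vector of covariate names to place on `Te`.
#' @param covariate_data Data frame with `study_id` and covariate columns.
#' @param quad_nodes Gauss-Hermite nodes per dimension.
#' @param sigma_fixed If non-NULL, the residual scale is fixed at this value
#'   rather than estimated.
#' @param random_effects Estimate study-level SDs (`TRUE`, requires >= 2
#'   studies) or fix them at 0.
#' @param control Passed to [stats::nlminb()].
#' @return An object of class `tte_fit`: the fitted [population_model()],
#'   an `estimates` table (estimate, SE, RSE%), `minus2LL`, `aic`, `k`,
#'   `study_effects`, and convergence diagnostics.
#' @export
fit_tte <- function(data, family, covariates = character(),
                    covariate_data = NULL, quad_nodes = 9,
                    sigma_fixed = NULL, random_effects = TRUE,
                    standard_errors = TRUE,
                    control = list(iter.max = 200, eval.max = 400)) {
  family <- match_family(family)
  data <- as.data.frame(data)
  stopifnot(all(c("study_id", "time", "obs", "se") %in% names(data)))
  n_studies <- length(unique(data$study_id))
  est_omega <- random_effects && n_studies >= 2L
  est_sigma <- is.null(sigma_fixed)
  k_theta <- length(covariates)
  b <- prep_batch(data, covariate_data, covariates)
  gh <- pracma::gaussHermite(quad_nodes)
  cache <- new.env(parent = emptyenv())

  par_names <- c("log_Te_pop", "log_p_pop",
                 if (k_theta) paste0("theta_", covariates),
                 if (est_omega) c("log_omega_Te", "log_omega_p"),
                 if (est_sigma) "log_sigma")
  unpack <- function(par) {
    i <- 2 + k_theta
    list(logTe = par[1], logp = par[2],
         theta = if (k_theta) stats::setNames(par[3:(2 + k_theta)], covariates) else numeric(0),
         omega = if (est_omega) exp(par[(i + 1):(i + 2)]) else c(0, 0),
         sigma = if (est_sigma) exp(par[length(par)]) else sigma_fixed)
  }
  negll <- function(par) {
    u <- unpack(par)
    res <- batch_marginal_ll(family, u$logTe, u$logp, u$theta, u$sigma,
                             u$omega, b, gh, cache)
    if (any(!is.finite(res$ll))) return(1e10)
    -sum(res$ll)
  }
  sv <- start_values(family, data)
  par0 <- c(sv[1], sv[2], rep(0, k_theta),
            if (est_omega) c(log(0.3), log(0.3)),
            if (est_sigma) log(1))
  lo <- c(log(1e-2), log(1e-2), rep(-5, k_theta),
          if (est_omega) rep(log(1e-3), 2), if (est_sigma) log(1e-3))
  hi <- c(log(1e4), log(50), rep(5, k_theta),
          if (est_omega) rep(log(3), 2), if (est_sigma) log(1e3))
  opt <- stats::nlminb(par0, negll, lower = lo, upper = hi, control = control)
  u <- unpack(opt$par)
  model <- population_model(family, Te_pop = exp(u$logTe), p_pop = exp(u$logp),
                            theta_cov = if (k_theta) as.list(u$theta) else NULL,
                            omega_Te = u$omega[1], omega_p = u$omega[2],
                            sigma = u$sigma)
  # SEs on the transformed scale, delta method back to natural scale
  se_t <- rep(NA_real_, length(opt$par))
  if (standard_errors) {
    Hn <- try(pracma::hessian(negll, opt$par), silent = TRUE)
    if (!inherits(Hn, "try-error") && all(is.finite(Hn))) {
      ev <- eigen(Hn, symmetric = TRUE, only.values = TRUE)$values
      if (all(ev > 0)) se_t <- sqrt(diag(solve(Hn)))
    }
  }
  est_nat <- c(exp(opt$par[1]), exp(opt$par[2]),
               if (k_theta) opt$par[3:(2 + k_theta)],
               if (est_omega) u$omega, if (est_sigma) u$sigma)
  is_log <- c(TRUE, TRUE, rep(FALSE, k_theta),
              if (est_omega) c(TRUE, TRUE), if (est_sigma) TRUE)
  se_nat <- ifelse(is_log, est_nat * se_t, se_t)
  nat_names <- c("Te_pop", "p_pop",
                 if (k_theta) paste0("theta_", covariates),
                 if (est_omega) c("omega_Te", "omega_p"),
                 if (est_sigma) "sigma")
  estimates <- data.frame(parameter = nat_names, estimate = est_nat,
                          se = se_nat,
                          rse_pct = 100 * se_nat / abs(est_nat))
  # empirical-Bayes study effects at the optimum
  final <- batch_marginal_ll(family, u$logTe, u$logp, u$theta, u$sigma,
                             u$omega, b, gh, cache)
  eff <- data.frame(study_id = b$study_ids,
                    eta_Te = final$eta[, 1], eta_p = final$eta[, 2])
  minus2LL <- 2 * opt$objective
  k <- length(opt$par)
  structure(list(model = model, estimates = estimates,
                 minus2LL = minus2LL, aic = minus2LL + 2 * k, k = k,
                 study_effects = eff,
                 convergence = list(code = opt$convergence,
                                    message = opt$message,
                                    iterations = opt$iterations,
                                    objective = opt$objective),
                 n_obs = nrow(data), n_studies = n_studies,
                 data_fingerprint = data_fingerprint(data),
                 quad_nodes = quad_nodes),
            class = "tte_fit")
}

data_fingerprint <- function(data) {
  c(n = nrow(data), sum_obs = round(sum(data$obs), 8),
    sum_t = round(sum(data$time), 6))
}

#' @export
print.tte_fit <- function(x, ...) {
  cat(sprintf("<tte_fit: %s, %d studies, %d obs>\n", x$model$family,
              x$n_studies, x$n_obs))
  print(x$estimates, digits = 4)
  cat(sprintf("-2LL = %.2f, AIC = %.2f (k = %d), convergence code %d\n",
              x$minus2LL, x$aic, x$k, x$convergence$code))
  invisible(x)
}

#' @export
AIC.tte_fit <- function(object, ..., k = 2) object$aic

#' Wald test of a parameter estimate
#'
#' Two-sided test of `estimate / se` against the standard normal, the screen
#' used to admit covariates at p < 0.05.
#'
#' @param estimate Point estimate.
#' @param se Standard error (> 0).
#' @return List with `z` and `p_value`.
#' @export
wald_test <- function(estimate, se) {
  if (!is.finite(se) || se <= 0) stop("`se` must be positive")
  z <- estimate / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Select the best model by AIC
#'
#' Returns the fit with minimum AIC among candidates estimated on identical
#' data; ties break toward fewer parameters.
#'
#' @param fits List of `tte_fit` objects.
#' @return The selected `tte_fit`, with attribute `selection_table`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "tte_fit")))
  fps <- lapply(fits, `[[`, "data_fingerprint")
  if (length(fits) > 1L &&
      !all(vapply(fps[-1], identical, TRUE, fps[[1]]))) {
    stop("candidate fits were estimated on different datasets")
  }
  tab <- data.frame(
    family = vapply(fits, function(f) f$model$family, ""),
    k = vapply(fits, `[[`, 0, "k"),
    minus2LL = vapply(fits, `[[`, 0, "minus2LL"),
    aic = vapply(fits, `[[`, 0, "aic"))
  ord <- order(tab$aic, tab$k)
  best <- fits[[ord[1]]]
  attr(best, "selection_table") <- tab[ord, , drop = FALSE]
  best
}

#' One-at-a-time Wald covariate screening
#'
#' Forward screen: each candidate covariate is added alone to the base model
#' and kept when its Wald p-value is below `alpha`.
#'
#' @param data Observation table.
#' @param family Hazard family.
#' @param candidates Character vector of covariate names.
#' @param covariate_data Data frame with `study_id` and covariate columns.
#' @param alpha Significance threshold (default 0.05).
#' @param ... Passed to [fit_tte()].
#' @return List with `log` (data frame: covariate, theta, se, z, p, kept)
#'   and `final` (the fit including all retained covariates).
#' @export
screen_covariates <- function(data, family, candidates, covariate_data,
                              alpha = 0.05, ...) {
  log_rows <- lapply(candidates, function(cv) {
    ft <- fit_tte(data, family, covariates = cv,
                  covariate_data = covariate_data, ...)
    row <- ft$estimates[ft$estimates$parameter == paste0("theta_", cv), ]
    w <- if (is.finite(row$se)) wald_test(row$estimate, row$se)
         else list(z = NA_real_, p_value = NA_real_)
    data.frame(covariate = cv, theta = row$estimate, se = row$se,
               z = w$z, p_value = w$p_value,
               kept = is.finite(w$p_value) && w$p_value < alpha)
  })
  log_df <- do.call(rbind, log_rows)
  kept <- log_df$covariate[log_df$kept]
  final <- fit_tte(data, family, covariates = kept,
                   covariate_data = covariate_data, ...)
  list(log = log_df, final = final)
}
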