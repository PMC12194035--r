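#' Parametric hazard families
#'
#' Three parametric time-to-event families are supported: Weibull, Gompertz
#' and log-logistic, written through their hazard functions
#' \deqn{h(t) = \lambda \gamma t^{\gamma-1} \quad \textrm{(Weibull)}}
#' \deqn{h(t) = \lambda e^{\gamma t} \quad \textrm{(Gompertz)}}
#' \deqn{h(t) = \lambda \gamma (\lambda t)^{\gamma-1} / (1 + (\lambda t)^\gamma)
#'   \quad \textrm{(log-logistic)}}
#' with \eqn{\lambda > 0} the risk scale at time 0 and \eqn{\gamma > 0} the
#' shape (regression rate). Survival is \eqn{S(t) = \exp(-H(t))} with the
#' closed-form cumulative hazard \eqn{H}. Time is measured in months
#' throughout.
#'
#' Alongside the \eqn{(\lambda, \gamma)} form, a natural \eqn{(T_e, p)}
#' parameterization is used for population models: \eqn{p \equiv \gamma} and
#' \eqn{T_e} a characteristic event time. For the Weibull and Gompertz
#' families \eqn{T_e} is the time at which the cumulative hazard reaches 1
#' (so \eqn{S(T_e) = e^{-1}}); for the log-logistic family \eqn{T_e = 1/\lambda},
#' which is the median (\eqn{S(T_e) = 0.5}). This convention reproduces the
#' published median survival times of the osimertinib models shipped with the
#' package.
#'
#' @param family One of `"weibull"`, `"gompertz"`, `"loglogistic"`.
#' @param lam,gam Positive rate and shape parameters \eqn{\lambda, \gamma}.
#' @param Te,p Positive characteristic time (months) and shape.
#' @return `hazard_params()` and `natural_params()` return classed parameter
#'   lists; the two round-trip losslessly via [to_natural()]/[from_natural()].
#' @examples
#' hp <- hazard_params("weibull", lam = 41.69^-2.25, gam = 2.25)
#' to_natural(hp)            # Te = 41.69, p = 2.25
#' tte_survival(hp, 41.69)   # exp(-1)
#' @name families
NULL

tte_families <- c("weibull", "gompertz", "loglogistic")

match_family <- function(family) {
  match.arg(tolower(family), tte_families)
}

#' @rdname families
#' @export
hazard_params <- function(family, lam, gam) {
  family <- match_family(family)
  stopifnot(is.numeric(lam), is.numeric(gam), length(lam) == 1L, length(gam) == 1L)
  if (!is.finite(lam) || lam <= 0) stop("`lam` must be a positive finite number")
  if (!is.finite(gam) || gam <= 0) stop("`gam` must be a positive finite number")
  structure(list(family = family, lam = lam, gam = gam), class = "hazard_params")
}

#' @rdname families
#' @export
natural_params <- function(family, Te, p) {
  family <- match_family(family)
  stopifnot(is.numeric(Te), is.numeric(p), length(Te) == 1L, length(p) == 1L)
  if (!is.finite(Te) || Te <= 0) stop("`Te` must be a positive finite number")
  if (!is.finite(p) || p <= 0) stop("`p` must be a positive finite number")
  structure(list(family = family, Te = Te, p = p), class = "natural_params")
}

#' @export
print.hazard_params <- function(x, ...) {
  cat(sprintf("<%s hazard: lambda = %.6g, gamma = %.6g>\n", x$family, x$lam, x$gam))
  invisible(x)
}

#' @export
print.natural_params <- function(x, ...) {
  cat(sprintf("<%s natural: Te = %.6g months, p = %.6g>\n", x$family, x$Te, x$p))
  invisible(x)
}

as_hazard_params <- function(params) {
  if (inherits(params, "hazard_params")) params
  else if (inherits(params, "natural_params")) from_natural(params)
  else stop("expected `hazard_params` or `natural_params`")
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("times must be finite and nonnegative")
  }
  as.numeric(t)
}

#' Hazard, cumulative hazard and survival
#'
#' Closed-form evaluation of the instantaneous hazard \eqn{h(t)}, cumulative
#' hazard \eqn{H(t)} and survival \eqn{S(t) = \exp(-H(t))} for the three
#' supported families. At `t = 0` the hazard diverges for shape < 1
#' (Weibull, log-logistic) and `Inf` is returned; `tte_survival(params, 0)`
#' is exactly 1. Likelihood code works with the cumulative hazard and never
#' evaluates the hazard at 0.
#'
#' @param params A [hazard_params()] or [natural_params()] object.
#' @param t Vector of nonnegative times (months).
#' @return Numeric vector the length of `t`.
#' @export
tte_hazard <- function(params, t) {
  hp <- as_hazard_params(params)
  t <- check_times(t)
  lam <- hp$lam; gam <- hp$gam
  switch(hp$family,
    weibull = lam * gam * t^(gam - 1),
    gompertz = lam * exp(gam * t),
    loglogistic = lam * gam * (lam * t)^(gam - 1) / (1 + (lam * t)^gam)
  )
}

#' @rdname tte_hazard
#' @export
tte_cumhaz <- function(params, t) {
  hp <- as_hazard_params(params)
  t <- check_times(t)
  lam <- hp$lam; gam <- hp$gam
  switch(hp$family,
    weibull = lam * t^gam,
    gompertz = lam / gam * (exp(gam * t) - 1),
    loglogistic = log1p((lam * t)^gam)
  )
}

#' @rdname tte_hazard
#' @export
tte_survival <- function(params, t) {
  exp(-tte_cumhaz(params, t))
}

#' Survival quantiles and event-time sampling
#'
#' `tte_quantile()` inverts the survival function: it returns the time `t`
#' with \eqn{S(t) = q}. The median is `tte_quantile(params, 0.5)`.
#' `tte_sample()` draws i.i.d. event times by inverse-CDF sampling.
#'
#' @param params A [hazard_params()] or [natural_params()] object.
#' @param q Survival probability level(s) in (0, 1).
#' @param n Number of draws.
#' @return Times in months.
#' @export
tte_quantile <- function(params, q) {
  hp <- as_hazard_params(params)
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    stop("`q` must lie strictly inside (0, 1)")
  }
  lam <- hp$lam; gam <- hp$gam
  H <- -log(q)  # target cumulative hazard
  switch(hp$family,
    weibull = (H / lam)^(1 / gam),
    gompertz = log1p(gam * H / lam) / gam,
    loglogistic = (expm1(H))^(1 / gam) / lam
  )
}

#' @rdname tte_quantile
#' @export
tte_sample <- function(params, n) {
  stopifnot(n >= 1)
  tte_quantile(params, stats::runif(n))
}

#' Convert between parameterizations
#'
#' `to_natural()` maps \eqn{(\lambda, \gamma)} to \eqn{(T_e, p)} under the
#' package convention (`p = gamma`; Weibull \eqn{T_e = \lambda^{-1/\gamma}},
#' Gompertz \eqn{T_e = \log(1 + \gamma/\lambda)/\gamma} so that
#' \eqn{H(T_e) = 1}, log-logistic \eqn{T_e = 1/\lambda}); `from_natural()`
#' is its exact inverse.
#'
#' @param hp A [hazard_params()] object.
#' @param np A [natural_params()] object.
#' @export
to_natural <- function(hp) {
  stopifnot(inherits(hp, "hazard_params"))
  lam <- hp$lam; gam <- hp$gam
  Te <- switch(hp$family,
    weibull = lam^(-1 / gam),
    gompertz = log1p(gam / lam) / gam,
    loglogistic = 1 / lam
  )
  natural_params(hp$family, Te = Te, p = gam)
}

#' @rdname to_natural
#' @export
from_natural <- function(np) {
  stopifnot(inherits(np, "natural_params"))
  Te <- np$Te; p <- np$p
  lam <- switch(np$family,
    weibull = Te^(-p),
    gompertz = p / expm1(p * Te),
    loglogistic = 1 / Te
  )
  hazard_params(np$family, lam = lam, gam = p)
}
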