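#' Specification of a synthetic multi-study trial dataset
#'
#' Describes the generating conditions for a bundle of trial arms with the
#' statistical structure assumed by the hierarchical curve model: study-level
#' lognormal parameter variability, a binary covariate mixed at a per-study
#' proportion, administrative plus random exponential censoring, and
#' "digitization" of the resulting KM curves onto a coarse sampling grid.
#'
#' @param n_studies Number of studies (arms).
#' @param subjects_per_study Integer count, or a length-2 range sampled
#'   uniformly per study.
#' @param model A [population_model()] giving the generating typical values,
#'   covariate coefficient and random-effect SDs.
#' @param cov_prop Proportion of subjects with covariate value 1 (e.g. the
#'   non-Asian fraction); scalar or per-study vector.
#' @param admin_cutoff Administrative censoring time, months.
#' @param dropout_rate Exponential random-censoring rate per month. The
#'   default 0.012 yields roughly half of overall-survival records censored
#'   at a 40-month cutoff, the maturity regime typical of the source trials.
#' @param points_per_curve Number of digitized coordinates per curve.
#' @param risk_interval Risk-table spacing, months.
#' @param jitter Half-width of uniform digitization noise on survival
#'   probabilities (default 0.005).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(n_studies, subjects_per_study, model,
                       cov_prop = 0, admin_cutoff = 40,
                       dropout_rate = 0.012,
                       points_per_curve = 40, risk_interval = 6,
                       jitter = 0.005, seed = 20301) {
  stopifnot(inherits(model, "population_model"),
            n_studies >= 1, all(subjects_per_study >= 1), admin_cutoff > 0)
  structure(list(n_studies = as.integer(n_studies),
                 subjects_per_study = subjects_per_study,
                 model = model,
                 cov_prop = rep_len(cov_prop, n_studies),
                 admin_cutoff = admin_cutoff,
                 dropout_rate = dropout_rate,
                 points_per_curve = as.integer(points_per_curve),
                 risk_interval = risk_interval,
                 jitter = jitter, seed = as.integer(seed)),
            class = "trial_spec")
}

#' Generate true individual patient data for a synthetic trial bundle
#'
#' Per study, random effects \eqn{\eta \sim N(0, \omega^2)} shift the
#' natural parameters on the log scale; per subject a covariate value is
#' drawn, an event time is sampled from the covariate-shifted model, and the
#' record is censored at the earlier of the administrative cutoff and an
#' exponential dropout time.
#'
#' @param spec A [trial_spec()].
#' @return Data frame with columns `time`, `event`, `study_id`, `arm`,
#'   `covariate`, plus attribute `truth` (per-study effects and sizes).
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  set.seed(spec$seed)
  m <- spec$model
  sizes <- if (length(spec$subjects_per_study) == 2L && spec$n_studies > 1L) {
    sample(spec$subjects_per_study[1]:spec$subjects_per_study[2],
           spec$n_studies, replace = TRUE)
  } else rep_len(spec$subjects_per_study, spec$n_studies)
  out <- vector("list", spec$n_studies)
  truth <- data.frame(study_id = sprintf("S%02d", seq_len(spec$n_studies)),
                      n = sizes, eta_Te = 0, eta_p = 0)
  for (i in seq_len(spec$n_studies)) {
    eta_Te <- stats::rnorm(1, 0, m$omega_Te)
    eta_p <- stats::rnorm(1, 0, m$omega_p)
    truth$eta_Te[i] <- eta_Te; truth$eta_p[i] <- eta_p
    n <- sizes[i]
    cv <- stats::rbinom(n, 1, spec$cov_prop[i])
    theta <- if (length(m$theta_cov)) m$theta_cov[[1]] else 0
    u <- stats::runif(n)
    tt <- numeric(n)
    for (val in unique(cv)) {
      sel <- cv == val
      np <- natural_params(m$family,
                           Te = m$Te_pop * exp(theta * val + eta_Te),
                           p = m$p_pop * exp(eta_p))
      tt[sel] <- tte_quantile(np, u[sel])
    }
    cens <- pmin(spec$admin_cutoff,
                 if (spec$dropout_rate > 0) stats::rexp(n, spec$dropout_rate) else Inf)
    out[[i]] <- data.frame(
      time = pmin(tt, cens),
      event = as.integer(tt <= cens),
      study_id = truth$study_id[i],
      arm = truth$study_id[i],
      covariate = cv
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- truth
  res
}

#' Digitize a synthetic arm's KM curve
#'
#' Emulates figure extraction: the KM estimate of the arm is sampled on an
#' equally spaced grid, small uniform jitter is optionally added to the
#' survival probabilities, the curve is repaired with [clean_curve()], and a
#' risk table is read off at the configured interval.
#'
#' @param ipd IPD data frame for a single arm (columns `time`, `event`).
#' @param spec A [trial_spec()] supplying grid, jitter and labels; or NULL
#'   to use defaults.
#' @param grid_times Optional explicit grid; overrides `points_per_curve`
#'   (use `km_estimate(ipd)$points$time` for full step resolution).
#' @param ... Passed to [digitized_curve()] (labels, endpoint, line).
#' @return A [digitized_curve()].
#' @export
digitize <- function(ipd, spec = NULL, grid_times = NULL, ...) {
  km <- km_estimate(ipd)
  n_pts <- if (is.null(spec)) 40L else spec$points_per_curve
  interval <- if (is.null(spec)) 6 else spec$risk_interval
  jit <- if (is.null(spec)) 0 else spec$jitter
  tmax <- max(km$points$time)
  if (is.null(grid_times)) {
    grid_times <- seq(0, tmax, length.out = n_pts)
  }
  sv <- step_surv(km$points, grid_times)
  if (jit > 0) sv <- sv + stats::runif(length(sv), -jit, jit)
  rt_times <- seq(0, tmax, by = interval)
  sm <- km_estimate(ipd, risk_times = rt_times)
  digitized_curve(points = data.frame(time = grid_times, surv = sv),
                  risk_table = sm$risk_table,
                  total_n = nrow(ipd), ...)
}

#' Deterministic benchmark fixture bundle
#'
#' Builds, from one seed, (a) a four-arm dataset mirroring the design of the
#' osimertinib OS meta-analysis (two first-line arms of 279 and 71 subjects
#' with 38% and 0% non-Asian mixes, generated from the published final
#' first-line Weibull model; two second-line arms of 129 and 279 subjects
#' from the published second-line log-logistic model), (b) a 20-study
#' parameter-recovery dataset, and (c) a tiny hand-checkable 8-subject
#' fixture.
#'
#' @param seed Integer master seed.
#' @return List with elements `arms` (list of lists: `ipd`, `curve`),
#'   `recovery` (list: `ipd`, `spec`), and `tiny` (IPD data frame).
#' @export
make_benchmark_suite <- function(seed = 20301) {
  pubs <- reference_models()
  os1 <- pubs$os_first_line_final
  os2 <- pubs$os_second_line_base
  arm_defs <- data.frame(
    study_id = c("FL-global", "FL-asia", "SL-a", "SL-b"),
    n = c(279L, 71L, 129L, 279L),
    cov_prop = c(0.38, 0, 0, 0),
    line = c("first", "first", "second", "second")
  )
  arms <- vector("list", nrow(arm_defs))
  for (i in seq_len(nrow(arm_defs))) {
    model <- if (arm_defs$line[i] == "first") os1 else os2
    sp <- trial_spec(1, arm_defs$n[i], model, cov_prop = arm_defs$cov_prop[i],
                     admin_cutoff = 44, seed = seed + i)
    ipd <- generate_trial(sp)
    ipd$study_id <- ipd$arm <- arm_defs$study_id[i]
    set.seed(seed + 100L + i)
    curve <- digitize(ipd, sp, study_id = arm_defs$study_id[i],
                      arm_label = arm_defs$study_id[i],
                      endpoint = "OS", line = arm_defs$line[i])
    arms[[i]] <- list(ipd = ipd, curve = curve)
  }
  names(arms) <- arm_defs$study_id
  rec_model <- population_model("weibull", Te_pop = 40, p_pop = 2.2,
                                omega_Te = 0.3, omega_p = 0.2, sigma = 1)
  rec_spec <- trial_spec(20, c(100, 400), rec_model, cov_prop = 0.4,
                         admin_cutoff = 40, seed = seed + 1000L)
  recovery <- list(ipd = generate_trial(rec_spec), spec = rec_spec)
  tiny <- data.frame(
    time = c(2, 4, 4, 6, 7, 9, 11, 12),
    event = c(1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L),
    study_id = "tiny", arm = "tiny", covariate = 0L
  )
  list(arms = arms, recovery = recovery, tiny = tiny)
}
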