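#' Pipeline configuration
#'
#' Reads a YAML (or JSON) configuration describing a full analysis: digitized
#' curve and risk-table files per arm, study-level covariates, candidate
#' families and fit options, and simulation scenarios. See the package
#' vignette for the schema; [write_example_config()] emits a working example.
#'
#' @param path Path to a YAML/JSON file, or a list with the same structure.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  if (!is.null(cfg$arms)) {
    ids <- vapply(cfg$arms, function(a) a$study_id %||% "", "")
    if (anyDuplicated(ids)) tte_input_error("duplicate arm study_id labels")
    for (a in cfg$arms) {
      for (f in c("curve", "risk_table")) {
        if (is.null(a[[f]])) {
          tte_input_error(sprintf("arm '%s': missing `%s` file entry",
                                  a$study_id %||% "?", f))
        }
      }
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tte_input_error <- function(msg) {
  stop(structure(class = c("ttemeta_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

tte_convergence_error <- function(msg) {
  stop(structure(class = c("ttemeta_convergence_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

tte_validation_error <- function(msg) {
  stop(structure(class = c("ttemeta_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

load_arm_curve <- function(a, base_dir = ".") {
  pathify <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  cf <- pathify(a$curve)
  rf <- pathify(a$risk_table)
  if (!file.exists(cf)) tte_input_error(sprintf("arm '%s': curve file not found: %s", a$study_id, a$curve))
  if (!file.exists(rf)) tte_input_error(sprintf("arm '%s': risk table not found: %s", a$study_id, a$risk_table))
  pts <- tryCatch(read_curve_csv(cf), error = function(e) tte_input_error(conditionMessage(e)))
  rt <- tryCatch(read_risk_table_csv(rf), error = function(e) tte_input_error(conditionMessage(e)))
  digitized_curve(pts, rt, total_n = a$total_n,
                  study_id = a$study_id, arm_label = a$arm_label %||% a$study_id,
                  endpoint = a$endpoint %||% "OS", line = a$line %||% "first",
                  total_events = a$total_events)
}

#' Pipeline stage: reconstruct pseudo-IPD for every configured arm
#'
#' Writes one IPD CSV per arm plus a `validation.json` of deviation
#' statistics under the configured output directory. Raises a validation
#' error when any arm's reconstruction deviates beyond `max_deviation`
#' (default 0.05).
#'
#' @param config A [pipeline_config()] (or path to one).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of per-arm validation reports.
#' @export
cmd_reconstruct <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (is.null(cfg$arms)) tte_input_error("config has no `arms` section")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tol <- cfg$max_deviation %||% 0.05
  reports <- list()
  for (a in cfg$arms) {
    t0 <- Sys.time()
    curve <- load_arm_curve(a, cfg$base_dir %||% ".")
    ipd <- reconstruct_ipd(curve)
    rep_ <- validate_reconstruction(curve, ipd)
    write_ipd_csv(ipd, file.path(cfg$out_dir, paste0("ipd_", a$study_id, ".csv")))
    reports[[a$study_id]] <- rep_
    if (!quiet) {
      message(sprintf("[reconstruct] %s: %d records, max dev %.4f (%.2fs)",
                      a$study_id, rep_$n_records, rep_$max_abs_dev,
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  jsonlite::write_json(reports, file.path(cfg$out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)
  bad <- names(reports)[vapply(reports, function(r) r$max_abs_dev > tol, TRUE)]
  if (length(bad)) {
    tte_validation_error(sprintf("reconstruction deviation above %.3f for arm(s): %s",
                                 tol, paste(bad, collapse = ", ")))
  }
  invisible(reports)
}

covariate_table <- function(cfg) {
  if (is.null(cfg$covariates)) return(NULL)
  do.call(rbind, lapply(cfg$covariates, as.data.frame))
}

#' Pipeline stage: fit candidate families and select by AIC
#'
#' Builds observation records from the configured curves, fits every
#' candidate family, optionally screens covariates by Wald test on the
#' AIC-best family, and writes per-fit JSONs plus a `selection.csv` table
#' sorted by AIC.
#'
#' @param config A [pipeline_config()] or path.
#' @param quiet Suppress progress messages.
#' @return Invisibly, list with `fits`, `selection`, `best`, and (when
#'   covariates were screened) `screening`.
#' @export
cmd_fit <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (is.null(cfg$arms)) tte_input_error("config has no `arms` section")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- lapply(cfg$arms, load_arm_curve, base_dir = cfg$base_dir %||% ".")
  data <- observation_records(curves)
  covd <- covariate_table(cfg)
  families <- cfg$fit$families %||% tte_families
  qn <- cfg$fit$quad_nodes %||% 9
  fits <- list()
  for (fam in families) {
    t0 <- Sys.time()
    ft <- tryCatch(fit_tte(data, fam, covariate_data = covd, quad_nodes = qn),
                   error = function(e) e)
    if (inherits(ft, "error")) {
      warning(sprintf("fit of %s failed and is excluded from selection: %s",
                      fam, conditionMessage(ft)))
      next
    }
    if (ft$convergence$code != 0 && !grepl("converg", ft$convergence$message %||% "",
                                           ignore.case = TRUE)) {
      warning(sprintf("fit of %s reported convergence code %d; excluded",
                      fam, ft$convergence$code))
      next
    }
    fits[[fam]] <- ft
    write_fit_json(ft, file.path(cfg$out_dir, paste0("fit_", fam, ".json")))
    if (!quiet) {
      message(sprintf("[fit] %s: AIC %.2f (%.2fs)", fam, ft$aic,
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  if (!length(fits)) tte_convergence_error("no candidate family converged")
  best <- select_model(fits)
  sel <- attr(best, "selection_table")
  screening <- NULL
  cand <- cfg$fit$covariates
  if (!is.null(cand) && length(cand)) {
    screening <- screen_covariates(data, best$model$family, unlist(cand),
                                   covariate_data = covd, quad_nodes = qn)
    utils::write.csv(screening$log, file.path(cfg$out_dir, "covariate_screen.csv"),
                     row.names = FALSE)
    best <- screening$final
    write_fit_json(best, file.path(cfg$out_dir, "fit_final.json"))
  }
  sel$selected <- sel$family == best$model$family
  utils::write.csv(sel, file.path(cfg$out_dir, "selection.csv"), row.names = FALSE)
  invisible(list(fits = fits, selection = sel, best = best, screening = screening))
}

#' Pipeline stage: run simulation scenarios
#'
#' Each configured scenario names a model (an explicit parameter block, a
#' fit JSON written by [cmd_fit()], or one of the published
#' [reference_models()]) plus a covariate mix; summaries are written as JSON
#' and, optionally, survival-band plots as PDF.
#'
#' @param config A [pipeline_config()] or path.
#' @param quiet Suppress progress messages.
#' @param plots Write percentile-band plots.
#' @return Invisibly, named list of `simulation_summary` objects.
#' @export
cmd_simulate <- function(config, quiet = FALSE, plots = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (is.null(cfg$scenarios)) tte_input_error("config has no `scenarios` section")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (sc in cfg$scenarios) {
    t0 <- Sys.time()
    model <- resolve_model(sc$model, cfg)
    mix <- if (is.null(sc$mix)) NULL else do.call(rbind, lapply(sc$mix, as.data.frame))
    if (!is.null(mix)) {
      extra <- setdiff(setdiff(names(mix), "weight"), names(model$theta_cov))
      if (length(extra)) {
        tte_input_error(sprintf("scenario '%s': unknown covariate stratum column(s): %s",
                                sc$name %||% "?", paste(extra, collapse = ", ")))
      }
    }
    scn <- simulation_scenario(model, covariate_mix = mix,
                               n_replicates = sc$n_replicates %||% 1000,
                               subjects_per_replicate = sc$subjects_per_replicate %||% 279,
                               landmark_times = unlist(sc$landmark_times %||% c(12, 36, 60)),
                               seed = sc$seed %||% cfg$seed)
    sm <- simulate_scenario(scn)
    nm <- sc$name %||% paste0("scenario", length(out) + 1)
    out[[nm]] <- sm
    jsonlite::write_json(list(median = sm$median,
                              landmark_rates = sm$landmark_rates,
                              percentile_bands = sm$percentile_bands),
                         file.path(cfg$out_dir, paste0("sim_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    utils::write.csv(sm$percentile_bands,
                     file.path(cfg$out_dir, paste0("sim_", nm, "_bands.csv")),
                     row.names = FALSE)
    if (plots) {
      grDevices::pdf(file.path(cfg$out_dir, paste0("sim_", nm, ".pdf")), 6, 4)
      plot(sm, main = nm)
      grDevices::dev.off()
    }
    if (!quiet) {
      message(sprintf("[simulate] %s: median %.2f mo (%.2fs)", nm,
                      sm$median$point, as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  invisible(out)
}

#' Pipeline stage: visual predictive check of a fitted model
#'
#' @param config A [pipeline_config()] or path; uses the `vpc` section
#'   (`model`, optional `n_sim`) and the configured arms for observations.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the `vpc_report`.
#' @export
cmd_vpc <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (is.null(cfg$arms)) tte_input_error("config has no `arms` section")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- lapply(cfg$arms, load_arm_curve, base_dir = cfg$base_dir %||% ".")
  data <- observation_records(curves)
  model <- resolve_model(cfg$vpc$model %||% "fit_final", cfg)
  rep_ <- vpc(model, data, covariate_data = covariate_table(cfg),
              n_sim = cfg$vpc$n_sim %||% 200, seed = cfg$seed)
  jsonlite::write_json(list(frac_in_band = rep_$frac_in_band, n_sim = rep_$n_sim),
                       file.path(cfg$out_dir, "vpc.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(rep_$table, file.path(cfg$out_dir, "vpc_table.csv"),
                   row.names = FALSE)
  if (!quiet) message(sprintf("[vpc] %.1f%% of observations in the 10-90 band",
                              100 * rep_$frac_in_band))
  invisible(rep_)
}

resolve_model <- function(spec, cfg) {
  if (inherits(spec, "population_model")) return(spec)
  if (is.character(spec) && length(spec) == 1L) {
    refs <- reference_models()
    if (spec %in% names(refs)) return(refs[[spec]])
    path <- spec
    if (!file.exists(path)) path <- file.path(cfg$out_dir, paste0(spec, ".json"))
    if (!file.exists(path)) tte_input_error(sprintf("model '%s' not found", spec))
    return(read_fit_json(path)$model)
  }
  if (is.list(spec)) {
    return(population_model(spec$family, Te_pop = spec$Te_pop, p_pop = spec$p_pop,
                            theta_cov = spec$theta_cov,
                            omega_Te = spec$omega_Te %||% 0,
                            omega_p = spec$omega_p %||% 0,
                            sigma = spec$sigma %||% 1))
  }
  tte_input_error("unrecognized model specification")
}

#' Serialize and restore fit results
#'
#' Fit results round-trip through JSON with all estimates, SEs, RSEs,
#' study effects, -2LL and AIC.
#'
#' @param fit A `tte_fit`.
#' @param path Output/input path.
#' @name fit_json
#' @export
write_fit_json <- function(fit, path) {
  m <- fit$model
  jsonlite::write_json(list(
    model = list(family = m$family, Te_pop = m$Te_pop, p_pop = m$p_pop,
                 theta_cov = as.list(m$theta_cov), omega_Te = m$omega_Te,
                 omega_p = m$omega_p, sigma = m$sigma),
    estimates = fit$estimates, minus2LL = fit$minus2LL, aic = fit$aic,
    k = fit$k, study_effects = fit$study_effects,
    convergence = fit$convergence, n_obs = fit$n_obs,
    n_studies = fit$n_studies), path,
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- x$model
  x$model <- population_model(m$family, Te_pop = m$Te_pop, p_pop = m$p_pop,
                              theta_cov = if (length(m$theta_cov)) m$theta_cov else NULL,
                              omega_Te = m$omega_Te, omega_p = m$omega_p,
                              sigma = m$sigma)
  class(x) <- "tte_fit"
  x
}

#' Write fixture files for the benchmark suite
#'
#' Materializes [make_benchmark_suite()] as the curve/risk-table/IPD CSV
#' dialects plus a manifest JSON carrying the generating truth.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return Invisibly, the manifest list.
#' @export
cmd_make_fixtures <- function(out_dir, seed = 20301) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  suite <- make_benchmark_suite(seed)
  manifest <- list(seed = seed, arms = list())
  for (nm in names(suite$arms)) {
    arm <- suite$arms[[nm]]
    utils::write.csv(data.frame(time = arm$curve$points$time,
                                survival = arm$curve$points$surv),
                     file.path(out_dir, paste0("curve_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(arm$curve$risk_table,
                     file.path(out_dir, paste0("risk_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    write_ipd_csv(arm$ipd, file.path(out_dir, paste0("ipd_", nm, ".csv")))
    manifest$arms[[nm]] <- list(total_n = arm$curve$total_n,
                                line = arm$curve$line,
                                n_events = sum(arm$ipd$event))
  }
  write_ipd_csv(suite$recovery$ipd, file.path(out_dir, "recovery_ipd.csv"))
  truth <- attr(suite$recovery$ipd, "truth")
  manifest$recovery <- list(model = unclass(suite$recovery$spec$model),
                            truth = truth)
  write_ipd_csv(suite$tiny, file.path(out_dir, "tiny_ipd.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(manifest)
}

#' Write an example pipeline configuration
#'
#' @param path Output YAML path.
#' @param fixtures_dir Directory holding fixture CSVs (see
#'   [cmd_make_fixtures()]).
#' @export
write_example_config <- function(path, fixtures_dir = ".") {
  cfg <- list(
    seed = 1, out_dir = "out", base_dir = fixtures_dir,
    arms = list(
      list(study_id = "FL-global", curve = "curve_FL-global.csv",
           risk_table = "risk_FL-global.csv", total_n = 279,
           endpoint = "OS", line = "first"),
      list(study_id = "FL-asia", curve = "curve_FL-asia.csv",
           risk_table = "risk_FL-asia.csv", total_n = 71,
           endpoint = "OS", line = "first")),
    covariates = list(
      list(study_id = "FL-global", race_nonasian = 0.38),
      list(study_id = "FL-asia", race_nonasian = 0)),
    fit = list(families = list("weibull", "loglogistic"),
               covariates = list("race_nonasian"), quad_nodes = 9),
    scenarios = list(
      list(name = "pooled", model = "os_first_line_final",
           mix = list(list(weight = 0.62, race_nonasian = 0),
                      list(weight = 0.38, race_nonasian = 1)),
           n_replicates = 1000, subjects_per_replicate = 279)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
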