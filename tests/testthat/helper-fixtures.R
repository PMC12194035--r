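# Shared fixtures, all generated in code.

tiny_ipd <- function() {
  data.frame(time = c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9),
             event = c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0))
}

# A digitized multi-study observation table with known generating truth.
make_obs_dataset <- function(n_studies = 8, seed = 301, family = "weibull",
                             Te = 40, p = 2.2, omega_Te = 0.3, omega_p = 0.2,
                             cov_prop = 0, points = 25, subjects = c(100, 300)) {
  m <- population_model(family, Te, p, omega_Te = omega_Te, omega_p = omega_p,
                        sigma = 1)
  sp <- trial_spec(n_studies, subjects, m, cov_prop = cov_prop,
                   admin_cutoff = 40, points_per_curve = points,
                   risk_interval = 6, seed = seed)
  ipd <- generate_trial(sp)
  set.seed(seed + 1)
  curves <- lapply(split(ipd, ipd$study_id), function(d) {
    digitize(d, sp, study_id = d$study_id[1], arm_label = d$study_id[1])
  })
  out <- observation_records(curves)
  attr(out, "truth") <- attr(ipd, "truth")
  out
}

random_params <- function(family, n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    hazard_params(family, lam = exp(runif(1, -6, 0.5)), gam = runif(1, 0.4, 5))
  })
}
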