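# compact world configurations shared across tests

# small binary covariate set: enough structure to split on, cheap to fit
small_covariates <- function() {
  list(
    female = list(type = "binary", p = 0.56),
    age = list(type = "categorical",
               levels = c("19_34", "35_49", "49_64"),
               probs = c(0.360, 0.365, 0.275), ref = "19_34"),
    white = list(type = "binary", p = 0.69),
    english = list(type = "binary", p = 0.90),
    depression = list(type = "binary", p = 0.34),
    hypertension = list(type = "binary", p = 0.18)
  )
}

# one gaussian outcome with configurable effect; intercept-only funnel
small_config <- function(n_households = 800,
                         effect = list(type = "constant", value = 1),
                         noise_sd = 1, crossover = 0.02,
                         apply_int = 0.6, approve_int = -0.1,
                         weights = list(type = "lognormal", sigma = 0.5),
                         baseline_coefs = c(depression = 2)) {
  dgp_config(
    n_households = n_households,
    covariate_spec = small_covariates(),
    apply_coefs = c(intercept = apply_int),
    approve_coefs = c(intercept = approve_int),
    control_crossover = crossover,
    outcome_specs = list(y1 = list(
      family = "gaussian",
      baseline = list(intercept = 0, coefs = baseline_coefs),
      noise_sd = noise_sd)),
    effect_spec = list(y1 = effect),
    weight_spec = weights)
}

quick_params <- function(n_trees = 150, ...) {
  forest_params(n_trees = n_trees, ...)
}
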