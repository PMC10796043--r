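#' Configuration of the synthetic lottery-design world
#'
#' Describes a household-randomized insurance-lottery experiment with known
#' ground truth: households are selected by lottery with probability
#' `p_select` (all members together), selected individuals may apply for
#' coverage and applications may be approved (both with covariate-dependent
#' log-odds), and a small fraction of non-selected controls obtain coverage
#' through other channels.  Outcomes are generated additively as
#' `Y = mu(X) + A * tau(X) + noise`, where the treatment channel `A` is the
#' lottery indicator Z (`effect_channel = "itt"`) or realized enrollment D
#' (`effect_channel = "treatment"`), so that the true average effect equals
#' the mean of `tau(X)` exactly.
#'
#' @param n_households Number of households.
#' @param household_size_probs Probability vector over household sizes 1-3
#'   (persons on the lottery list per household); must sum to one.
#' @param p_select Lottery selection probability per household.
#' @param covariate_spec Named list of covariate definitions: each element is
#'   `list(type = "binary", p = prevalence)` or `list(type = "categorical",
#'   levels =, probs =, ref =)`.  Categorical covariates expand to one 0/1
#'   indicator column per non-reference level.  Defaults mirror the
#'   baseline-covariate prevalences of the motivating in-person lottery
#'   sample (female 56%, white 69%, depression 34%, ...).
#' @param apply_coefs Named numeric: intercept plus per-covariate log-odds
#'   coefficients for applying given lottery selection (names must match
#'   expanded covariate columns; use `"intercept"` for the intercept).
#' @param approve_coefs Same, for approval given application.
#' @param control_crossover Probability that a non-selected person is
#'   enrolled anyway (default 2%, matching the roughly two percent of
#'   controls that obtain standard coverage through alternative routes).
#' @param outcome_specs Named list of outcome definitions; each element has
#'   `family` (one of `"gaussian"`, `"poisson"`, `"zero-inflated-lognormal"`),
#'   a `baseline` (`list(intercept =, coefs =)` or a function of the
#'   covariate matrix) and family-specific noise fields (`noise_sd`;
#'   `p_spend` and `sigma_log` for the semicontinuous spending family).
#' @param effect_spec Named list (one per outcome) of true-effect functions
#'   tau(X): `list(type = "constant", value =)`,
#'   `list(type = "linear", intercept =, coefs = c(name = slope, ...))`, or
#'   `list(type = "step", covariate =, value_in =, value_out =)`.
#' @param effect_channel `"itt"` (tau acts through Z) or `"treatment"`
#'   (through D).
#' @param weight_spec `list(type = "unit")` or
#'   `list(type = "lognormal", sigma =)`; lognormal survey weights are
#'   normalized to mean one.
#'
#' @return An object of class `"dgp_config"`.
#' @export
dgp_config <- function(n_households = 5000L,
                       household_size_probs = c(0.755, 0.243, 0.002),
                       p_select = 0.5,
                       covariate_spec = default_covariate_spec(),
                       apply_coefs = default_apply_coefs(),
                       approve_coefs = default_approve_coefs(),
                       control_crossover = 0.02,
                       outcome_specs = default_outcome_specs(),
                       effect_spec = default_effect_spec(),
                       effect_channel = c("itt", "treatment"),
                       weight_spec = list(type = "lognormal", sigma = 0.5)) {
  effect_channel <- match.arg(effect_channel)
  n_households <- as.integer(n_households)
  if (is.na(n_households) || n_households < 1L) {
    stop("n_households must be a positive integer", call. = FALSE)
  }
  if (abs(sum(household_size_probs) - 1) > 1e-12 ||
      any(household_size_probs < 0)) {
    stop("household_size_probs must be nonnegative and sum to 1",
         call. = FALSE)
  }
  for (fld in c("p_select", "control_crossover")) {
    v <- get(fld)
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(sprintf("%s must lie in [0, 1]", fld), call. = FALSE)
    }
  }
  for (nm in names(covariate_spec)) {
    cs <- covariate_spec[[nm]]
    if (identical(cs$type, "binary")) {
      if (cs$p < 0 || cs$p > 1) {
        stop(sprintf("covariate_spec$%s: prevalence must lie in [0, 1]", nm),
             call. = FALSE)
      }
    } else if (identical(cs$type, "categorical")) {
      if (any(cs$probs < 0) || abs(sum(cs$probs) - 1) > 1e-12) {
        stop(sprintf(
          "covariate_spec$%s: probabilities must be nonnegative and sum to 1",
          nm), call. = FALSE)
      }
      if (length(cs$levels) != length(cs$probs)) {
        stop(sprintf("covariate_spec$%s: levels and probs differ in length",
                     nm), call. = FALSE)
      }
    } else {
      stop(sprintf("covariate_spec$%s: unknown type", nm), call. = FALSE)
    }
  }
  cfg <- structure(
    list(
      n_households = n_households,
      household_size_probs = household_size_probs,
      p_select = p_select,
      covariate_spec = covariate_spec,
      apply_coefs = apply_coefs,
      approve_coefs = approve_coefs,
      control_crossover = control_crossover,
      outcome_specs = outcome_specs,
      effect_spec = effect_spec,
      effect_channel = effect_channel,
      weight_spec = weight_spec
    ),
    class = "dgp_config"
  )
  cols <- dgp_covariate_columns(cfg)
  check_names <- function(coefs, field) {
    bad <- setdiff(setdiff(names(coefs), "intercept"), cols)
    if (length(bad) > 0) {
      stop(sprintf("%s names not in covariate_spec: %s", field,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_names(apply_coefs, "apply_coefs")
  check_names(approve_coefs, "approve_coefs")
  for (nm in names(effect_spec)) {
    es <- effect_spec[[nm]]
    if (identical(es$type, "linear")) check_names(es$coefs, "effect_spec")
    if (identical(es$type, "step") && !(es$covariate %in% cols)) {
      stop(sprintf("effect_spec$%s: unknown covariate '%s'", nm,
                   es$covariate), call. = FALSE)
    }
  }
  if (!identical(sort(names(outcome_specs)), sort(names(effect_spec)))) {
    stop("effect_spec must name exactly the outcomes in outcome_specs",
         call. = FALSE)
  }
  cfg
}

#' @rdname dgp_config
#' @export
default_covariate_spec <- function() {
  list(
    female = list(type = "binary", p = 0.56),
    age = list(type = "categorical",
               levels = c("19_34", "35_49", "49_64"),
               probs = c(0.360, 0.365, 0.275), ref = "19_34"),
    race = list(type = "categorical",
                levels = c("white", "black", "hispanic", "none"),
                probs = c(0.690, 0.100, 0.175, 0.035), ref = "none"),
    other_race = list(type = "binary", p = 0.15),
    english = list(type = "binary", p = 0.90),
    asthma = list(type = "binary", p = 0.19),
    diabetes = list(type = "binary", p = 0.07),
    hypertension = list(type = "binary", p = 0.18),
    high_cholesterol = list(type = "binary", p = 0.125),
    heart_attack = list(type = "binary", p = 0.019),
    chf = list(type = "binary", p = 0.010),
    copd = list(type = "binary", p = 0.022),
    kidney_failure = list(type = "binary", p = 0.017),
    cancer = list(type = "binary", p = 0.043),
    depression = list(type = "binary", p = 0.34)
  )
}

# expanded covariate column names implied by a config (19 with the defaults:
# 15 binaries + 2 age indicators + 3 race indicators + household-size flag,
# minus the two categorical reference levels)
dgp_covariate_columns <- function(config) {
  cols <- character(0)
  for (nm in names(config$covariate_spec)) {
    cs <- config$covariate_spec[[nm]]
    if (identical(cs$type, "binary")) {
      cols <- c(cols, nm)
    } else {
      ref <- cs$ref %||% cs$levels[1]
      keep <- setdiff(cs$levels, ref)
      cols <- c(cols, paste(nm, keep, sep = "_"))
    }
  }
  c(cols, "hh2plus")
}

#' @rdname dgp_config
#' @export
default_apply_coefs <- function() {
  # marginal application rate among the selected near 64%, rising with age
  # (age heterogeneity enters mostly at the application stage)
  c(intercept = 0.40, age_35_49 = 0.15, age_49_64 = 0.40, english = 0.10)
}

#' @rdname dgp_config
#' @export
default_approve_coefs <- function() {
  # marginal approval rate among applicants near 48%, higher for whites and
  # English-preferring applicants (race heterogeneity at the approval stage)
  c(intercept = -0.55, race_white = 0.35, english = 0.25)
}

#' @rdname dgp_config
#' @export
default_outcome_specs <- function() {
  list(
    mcs = list(family = "gaussian",
               baseline = list(intercept = 48,
                               coefs = c(depression = -6, age_49_64 = -1)),
               noise_sd = 9),
    pcs = list(family = "gaussian",
               baseline = list(intercept = 50,
                               coefs = c(hypertension = -2, age_49_64 = -4,
                                         asthma = -1.5)),
               noise_sd = 9),
    oop_spending = list(family = "zero-inflated-lognormal",
                        baseline = list(intercept = 400,
                                        coefs = c(age_49_64 = 150,
                                                  high_cholesterol = 100)),
                        p_spend = 0.55, sigma_log = 1.3),
    rx_drugs = list(family = "poisson",
                    baseline = list(intercept = 1.2,
                                    coefs = c(depression = 1.5,
                                              hypertension = 1.2,
                                              age_49_64 = 0.8))),
    office_visits = list(family = "poisson",
                         baseline = list(intercept = 1.6,
                                         coefs = c(depression = 1.0,
                                                   age_49_64 = 0.8))),
    hospital_admissions = list(family = "poisson",
                               baseline = list(intercept = 0.06,
                                               coefs = c(chf = 0.3))),
    outpatient_surgery = list(family = "poisson",
                              baseline = list(intercept = 0.05,
                                              coefs = NULL)),
    ed_visits = list(family = "poisson",
                     baseline = list(intercept = 0.35,
                                     coefs = c(depression = 0.25)))
  )
}

#' @rdname dgp_config
#' @export
default_effect_spec <- function() {
  list(
    mcs = list(type = "constant", value = 0.5),
    pcs = list(type = "constant", value = 0.3),
    oop_spending = list(type = "constant", value = -60),
    rx_drugs = list(type = "constant", value = 0.18),
    office_visits = list(type = "constant", value = 0.57),
    hospital_admissions = list(type = "constant", value = 0.01),
    outpatient_surgery = list(type = "constant", value = 0.005),
    ed_visits = list(type = "constant", value = 0.01)
  )
}

eval_baseline <- function(baseline, X) {
  if (is.function(baseline)) {
    return(as.numeric(baseline(X)))
  }
  mu <- rep(baseline$intercept, nrow(X))
  for (nm in names(baseline$coefs)) {
    if (!nm %in% colnames(X)) {
      stop(sprintf("baseline references unknown covariate '%s'", nm),
           call. = FALSE)
    }
    mu <- mu + baseline$coefs[[nm]] * X[, nm]
  }
  mu
}

eval_linear_index <- function(coefs, X) {
  eta <- rep(if ("intercept" %in% names(coefs)) coefs[["intercept"]] else 0,
             nrow(X))
  for (nm in setdiff(names(coefs), "intercept")) {
    eta <- eta + coefs[[nm]] * X[, nm]
  }
  eta
}

#' Serialize a world configuration to JSON
#'
#' Writes a [dgp_config()] to a structured JSON file and reads it back.
#' Baseline and effect functions given as coefficient lists round-trip
#' exactly; baselines supplied as R functions are not serializable and are
#' rejected.
#'
#' @param config A [dgp_config()].
#' @param path JSON file path.
#' @export
write_dgp_config <- function(config, path) {
  stopifnot(inherits(config, "dgp_config"))
  for (os in config$outcome_specs) {
    if (is.function(os$baseline)) {
      stop("function-valued baselines cannot be serialized; use coefficient form",
           call. = FALSE)
    }
  }
  prep <- unclass(config)
  # named coefficient vectors must serialize as JSON objects, not arrays
  prep$apply_coefs <- as.list(prep$apply_coefs)
  prep$approve_coefs <- as.list(prep$approve_coefs)
  for (nm in names(prep$outcome_specs)) {
    b <- prep$outcome_specs[[nm]]$baseline
    if (!is.null(b$coefs)) {
      prep$outcome_specs[[nm]]$baseline$coefs <- as.list(b$coefs)
    }
  }
  for (nm in names(prep$effect_spec)) {
    if (identical(prep$effect_spec[[nm]]$type, "linear")) {
      prep$effect_spec[[nm]]$coefs <- as.list(prep$effect_spec[[nm]]$coefs)
    }
  }
  jsonlite::write_json(prep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dgp_config
#' @export
read_dgp_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  relist_coefs <- function(x) {
    y <- if (is.list(x)) unlist(x) else x
    storage.mode(y) <- "double"
    y
  }
  as_dbl <- function(x) if (is.null(x)) NULL else as.numeric(x)
  for (nm in names(raw$covariate_spec)) {
    cs <- raw$covariate_spec[[nm]]
    if (identical(cs$type, "categorical")) {
      raw$covariate_spec[[nm]]$levels <- unlist(cs$levels)
      raw$covariate_spec[[nm]]$probs <- unlist(cs$probs)
    }
  }
  raw$apply_coefs <- relist_coefs(raw$apply_coefs)
  raw$approve_coefs <- relist_coefs(raw$approve_coefs)
  raw$household_size_probs <- unlist(raw$household_size_probs)
  for (nm in names(raw$outcome_specs)) {
    os <- raw$outcome_specs[[nm]]
    if (!is.null(os$baseline$coefs)) {
      raw$outcome_specs[[nm]]$baseline$coefs <- relist_coefs(os$baseline$coefs)
    }
    for (fld in c("noise_sd", "p_spend", "sigma_log")) {
      raw$outcome_specs[[nm]][[fld]] <- as_dbl(os[[fld]])
    }
    raw$outcome_specs[[nm]]$baseline$intercept <- as_dbl(os$baseline$intercept)
  }
  for (nm in names(raw$effect_spec)) {
    es <- raw$effect_spec[[nm]]
    if (identical(es$type, "linear")) {
      raw$effect_spec[[nm]]$coefs <- relist_coefs(es$coefs)
    }
    for (fld in c("value", "value_in", "value_out")) {
      raw$effect_spec[[nm]][[fld]] <- as_dbl(es[[fld]])
    }
  }
  raw$p_select <- as_dbl(raw$p_select)
  raw$control_crossover <- as_dbl(raw$control_crossover)
  if (!is.null(raw$weight_spec$sigma)) {
    raw$weight_spec$sigma <- as_dbl(raw$weight_spec$sigma)
  }
  for (nm in names(raw$covariate_spec)) {
    if (!is.null(raw$covariate_spec[[nm]]$p)) {
      raw$covariate_spec[[nm]]$p <- as_dbl(raw$covariate_spec[[nm]]$p)
    }
  }
  do.call(dgp_config, raw)
}

#' True conditional average treatment effect of a configured world
#'
#' Evaluates the configured effect function tau(X) for one outcome on a
#' covariate matrix -- the ground truth against which estimated CATEs are
#' benchmarked.
#'
#' @param config A [dgp_config()].
#' @param X Covariate matrix with columns named as in the configuration's
#'   expanded covariate set.
#' @param outcome Outcome name or index (default: first outcome).
#' @return Numeric vector `tau(X)`, one value per row of `X`.
#' @export
true_cate <- function(config, X, outcome = 1L) {
  stopifnot(inherits(config, "dgp_config"))
  nm <- if (is.character(outcome)) outcome else names(config$effect_spec)[outcome]
  es <- config$effect_spec[[nm]]
  if (is.null(es)) stop(sprintf("unknown outcome '%s'", nm), call. = FALSE)
  switch(es$type,
    constant = rep(es$value, nrow(X)),
    linear = {
      bad <- setdiff(setdiff(names(es$coefs), "intercept"), colnames(X))
      if (length(bad) > 0) {
        stop(sprintf("effect_spec references unknown covariates: %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      eval_linear_index(es$coefs, X)
    },
    step = {
      if (!es$covariate %in% colnames(X)) {
        stop(sprintf("effect_spec references unknown covariate '%s'",
                     es$covariate), call. = FALSE)
      }
      ifelse(X[, es$covariate] == 1, es$value_in, es$value_out)
    },
    stop(sprintf("unknown effect type '%s'", es$type), call. = FALSE)
  )
}

#' Generate a synthetic lottery sample with known ground truth
#'
#' Draws a full person-level sample from a configured world: household sizes
#' and household-level lottery selection, independent baseline covariates,
#' the application/approval enrollment funnel, control crossover, survey
#' weights, and all configured outcomes.  Identical `(config, seed)` pairs
#' reproduce the sample exactly; every generation stage draws from its own
#' seed substream, so changing one stage's configuration does not perturb the
#' draws of the others.
#'
#' @param config A [dgp_config()].
#' @param seed Integer seed.
#' @return A list with components `sample` (a validated `hf_sample`
#'   data frame) and `truth` (list with the per-person true effect matrix
#'   `tau`, one column per outcome, and `compliance_prob`, the per-person
#'   difference in enrollment probability between selection arms).
#' @export
generate_sample <- function(config, seed) {
  stopifnot(inherits(config, "dgp_config"))

  hh_size <- with_substream(seed, "households", {
    sample.int(length(config$household_size_probs), config$n_households,
               replace = TRUE, prob = config$household_size_probs)
  })
  z_hh <- with_substream(seed, "lottery", {
    stats::rbinom(config$n_households, 1L, config$p_select)
  })
  household_id <- rep(seq_len(config$n_households), times = hh_size)
  n <- length(household_id)
  Z <- z_hh[household_id]

  # covariates, each from its own substream
  cols <- list()
  labels <- list()
  for (nm in names(config$covariate_spec)) {
    cs <- config$covariate_spec[[nm]]
    if (identical(cs$type, "binary")) {
      cols[[nm]] <- with_substream(seed, paste0("cov:", nm), {
        stats::rbinom(n, 1L, cs$p)
      })
    } else {
      lev <- with_substream(seed, paste0("cov:", nm), {
        sample(cs$levels, n, replace = TRUE, prob = cs$probs)
      })
      labels[[nm]] <- lev
      ref <- cs$ref %||% cs$levels[1]
      for (lv in setdiff(cs$levels, ref)) {
        cols[[paste(nm, lv, sep = "_")]] <- as.integer(lev == lv)
      }
    }
  }
  cols[["hh2plus"]] <- as.integer(hh_size[household_id] >= 2L)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  storage.mode(X) <- "double"

  p_apply <- stats::plogis(eval_linear_index(config$apply_coefs, X))
  p_approve <- stats::plogis(eval_linear_index(config$approve_coefs, X))
  apply_draw <- with_substream(seed, "apply", stats::rbinom(n, 1L, p_apply))
  approve_draw <- with_substream(seed, "approve",
                                 stats::rbinom(n, 1L, p_approve))
  applied <- Z * apply_draw
  approved <- applied * approve_draw
  crossover <- with_substream(seed, "crossover", {
    stats::rbinom(n, 1L, config$control_crossover)
  })
  D <- as.integer(applied * approved == 1L | (Z == 0L & crossover == 1L))

  w <- if (identical(config$weight_spec$type, "unit")) {
    rep(1, n)
  } else {
    raw <- with_substream(seed, "weights", {
      stats::rlnorm(n, meanlog = 0, sdlog = config$weight_spec$sigma)
    })
    raw / mean(raw)
  }

  out_names <- names(config$outcome_specs)
  tau <- sapply(out_names, function(nm) true_cate(config, X, nm))
  tau <- matrix(tau, nrow = n, dimnames = list(NULL, out_names))
  A <- if (identical(config$effect_channel, "itt")) Z else D

  Y <- matrix(NA_real_, n, length(out_names),
              dimnames = list(NULL, paste0("y_", out_names)))
  for (j in seq_along(out_names)) {
    os <- config$outcome_specs[[j]]
    mu <- eval_baseline(os$baseline, X)
    Y[, j] <- with_substream(seed, paste0("outcome:", out_names[j]), {
      switch(os$family,
        gaussian = mu + A * tau[, j] + stats::rnorm(n, 0, os$noise_sd),
        poisson = stats::rpois(n, pmax(mu + A * tau[, j], 0)),
        `zero-inflated-lognormal` = {
          spend <- stats::rbinom(n, 1L, os$p_spend)
          amount <- stats::rlnorm(n, meanlog = log(pmax(mu, 1e-8)),
                                  sdlog = os$sigma_log)
          spend * amount + A * tau[, j]
        },
        stop(sprintf("unknown outcome family '%s'", os$family), call. = FALSE)
      )
    })
  }

  age_band <- if (!is.null(labels$age)) labels$age else rep(NA_character_, n)
  df <- data.frame(
    person_id = seq_len(n),
    household_id = household_id,
    Z = as.integer(Z),
    applied = as.integer(applied),
    approved = as.integer(approved),
    D = D,
    weight = w,
    sex = if ("female" %in% colnames(X)) {
      ifelse(X[, "female"] == 1, "female", "male")
    } else {
      NA_character_
    },
    age_band = age_band,
    white = if ("race_white" %in% colnames(X)) {
      as.integer(X[, "race_white"])
    } else if ("white" %in% colnames(X)) {
      as.integer(X[, "white"])
    } else {
      NA_integer_
    },
    high_risk = as.integer(rowSums(X[, intersect(
      c("diabetes", "hypertension", "high_cholesterol", "heart_attack",
        "chf"), colnames(X)), drop = FALSE]) > 0),
    depressed = if ("depression" %in% colnames(X)) {
      as.integer(X[, "depression"])
    } else {
      NA_integer_
    },
    stringsAsFactors = FALSE
  )
  Xdf <- as.data.frame(X)
  names(Xdf) <- paste0("x_", colnames(X))
  df <- cbind(df, Xdf, as.data.frame(Y))
  sample <- as_hf_sample(df)
  validate_sample(sample)

  list(
    sample = sample,
    truth = list(
      tau = tau,
      compliance_prob = p_apply * p_approve - config$control_crossover
    )
  )
}
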