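#' Person-level observational samples
#'
#' An `hf_sample` is a validated person-level data frame for lottery-design
#' analyses: identifiers (`person_id`, `household_id`), the binary lottery
#' instrument `Z`, enrollment-funnel flags (`applied`, `approved`), realized
#' enrollment `D`, a positive survey weight `weight`, baseline covariate
#' columns prefixed `x_`, outcome columns prefixed `y_`, and derived subgroup
#' labels (`sex`, `age_band`, `white`, `high_risk`, `depressed`).
#'
#' @param df A data frame with the columns described above.
#' @return `df` with class `hf_sample` and covariate/outcome attributes.
#' @export
as_hf_sample <- function(df) {
  required <- c("person_id", "household_id", "Z", "D", "weight")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("sample schema error: missing required column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"applied" %in% names(df)) df$applied <- NA_integer_
  if (!"approved" %in% names(df)) df$approved <- NA_integer_
  attr(df, "covariates") <- grep("^x_", names(df), value = TRUE)
  attr(df, "outcomes") <- grep("^y_", names(df), value = TRUE)
  class(df) <- c("hf_sample", "data.frame")
  df
}

#' @rdname as_hf_sample
#' @param sample An `hf_sample`.
#' @export
validate_sample <- function(sample) {
  stopifnot(inherits(sample, "hf_sample"))
  check_binary <- function(col) {
    v <- sample[[col]]
    v <- v[!is.na(v)]
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad) > 0) {
      stop(sprintf("non-binary value in column '%s' (first at row %d)",
                   col, bad[1]), call. = FALSE)
    }
  }
  for (col in c("Z", "D", "applied", "approved")) check_binary(col)
  if (any(!is.finite(sample$weight)) || any(sample$weight <= 0)) {
    stop("weights must be strictly positive and finite", call. = FALSE)
  }
  has_funnel <- !all(is.na(sample$applied))
  if (has_funnel) {
    bad <- which(sample$approved == 1 & sample$applied == 0)
    if (length(bad) > 0) {
      stop(sprintf(
        "funnel invariant violated: approved = 1 with applied = 0 (row %d)",
        bad[1]), call. = FALSE)
    }
    bad <- which(sample$Z == 0 & sample$applied == 1)
    if (length(bad) > 0) {
      stop(sprintf(
        "funnel invariant violated: applied = 1 with Z = 0 (row %d)",
        bad[1]), call. = FALSE)
    }
  }
  z_per_hh <- tapply(sample$Z, sample$household_id,
                     function(z) length(unique(z)))
  if (any(z_per_hh > 1)) {
    stop("lottery selection must be constant within household", call. = FALSE)
  }
  invisible(sample)
}

#' Extract the covariate matrix of a sample
#'
#' @param sample An `hf_sample`.
#' @param covariates Optional subset of covariate names (without the `x_`
#'   prefix) to extract, in the given order.
#' @return Numeric matrix with unprefixed column names.
#' @export
covariate_matrix <- function(sample, covariates = NULL) {
  cols <- attr(sample, "covariates")
  X <- as.matrix(sample[, cols, drop = FALSE])
  colnames(X) <- sub("^x_", "", cols)
  if (!is.null(covariates)) {
    missing <- setdiff(covariates, colnames(X))
    if (length(missing) > 0) {
      stop(sprintf("unknown covariate(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    X <- X[, covariates, drop = FALSE]
  }
  storage.mode(X) <- "double"
  X
}

#' Prespecified subgroup masks
#'
#' Builds the prespecified subgroup system used throughout the analysis: the
#' overall mask plus 21 subgroups (sex, age band, white/non-white, high-risk
#' status, depression status, age-by-sex, and race-by-sex cells).
#'
#' @param sample An `hf_sample` with populated subgroup label columns.
#' @return Named list of 22 logical masks; `overall` is all-`TRUE`.  Sex,
#'   age-band, race, high-risk and depression masks each partition the
#'   sample.
#' @export
make_subgroups <- function(sample) {
  need <- c("sex", "age_band", "white", "high_risk", "depressed")
  for (col in need) {
    if (!col %in% names(sample) || all(is.na(sample[[col]]))) {
      stop(sprintf("subgroup label column '%s' is missing or empty", col),
           call. = FALSE)
    }
  }
  n <- nrow(sample)
  male <- sample$sex == "male"
  female <- sample$sex == "female"
  ages <- c("19_34", "35_49", "49_64")
  white <- sample$white == 1
  masks <- list(overall = rep(TRUE, n), male = male, female = female)
  for (a in ages) masks[[paste0("age_", a)]] <- sample$age_band == a
  masks$white <- white
  masks$non_white <- !white
  masks$high_risk <- sample$high_risk == 1
  masks$non_high_risk <- sample$high_risk == 0
  masks$depressed <- sample$depressed == 1
  masks$non_depressed <- sample$depressed == 0
  for (a in ages) {
    masks[[paste0("age_", a, "_female")]] <- sample$age_band == a & female
  }
  for (a in ages) {
    masks[[paste0("age_", a, "_male")]] <- sample$age_band == a & male
  }
  masks$white_female <- white & female
  masks$non_white_female <- !white & female
  masks$white_male <- white & male
  masks$non_white_male <- !white & male
  masks
}

#' @export
print.hf_sample <- function(x, ...) {
  cat(sprintf(
    "hf_sample: %d persons in %d households (%d covariates, %d outcomes)\n",
    nrow(x), length(unique(x$household_id)),
    length(attr(x, "covariates")), length(attr(x, "outcomes"))))
  cat(sprintf("  selected: %.1f%%; enrolled: %.1f%%\n",
              100 * mean(x$Z), 100 * mean(x$D)))
  invisible(x)
}
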