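#' Read a person-level sample from CSV
#'
#' Reads an RFC-4180 CSV with a header row (or a Stata `.dta` table, which
#' is converted on load) into a validated `hf_sample`.  Column names may be
#' remapped through `mapping` (useful for public-use distributions whose
#' layouts vary between releases).  Rows with missing
#' values in required columns are dropped with a message; row order is
#' preserved.  Subgroup label columns are derived from the covariates when
#' absent.
#'
#' @param path CSV file path.
#' @param mapping Optional named character vector `c(file_column =
#'   canonical_name, ...)` applied before validation.
#' @return A validated `hf_sample`.
#' @export
read_sample <- function(path, mapping = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- read_table_any(path)
  if (!is.null(mapping)) {
    idx <- match(names(mapping), names(df))
    if (anyNA(idx)) {
      stop(sprintf("mapping refers to absent column(s): %s",
                   paste(names(mapping)[is.na(idx)], collapse = ", ")),
           call. = FALSE)
    }
    names(df)[idx] <- unname(mapping)
  }
  required <- c("person_id", "household_id", "Z", "D", "weight")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("sample schema error: missing required column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  check_cols <- c(required, grep("^x_|^y_", names(df), value = TRUE),
                  intersect(c("applied", "approved"), names(df)))
  complete <- stats::complete.cases(df[, check_cols, drop = FALSE])
  if (any(!complete)) {
    message(sprintf("dropping %d row(s) with missing required fields",
                    sum(!complete)))
    df <- df[complete, , drop = FALSE]
  }
  df <- derive_labels(df)
  sample <- as_hf_sample(df)
  validate_sample(sample)
  sample
}

# fill sex / age_band / white / high_risk / depressed from covariate columns
# when the label columns are absent
derive_labels <- function(df) {
  has <- function(nm) paste0("x_", nm) %in% names(df)
  cov <- function(nm) df[[paste0("x_", nm)]]
  if (!"sex" %in% names(df) && has("female")) {
    df$sex <- ifelse(cov("female") == 1, "female", "male")
  }
  if (!"age_band" %in% names(df) && has("age_35_49") && has("age_49_64")) {
    df$age_band <- ifelse(cov("age_49_64") == 1, "49_64",
                          ifelse(cov("age_35_49") == 1, "35_49", "19_34"))
  }
  if (!"white" %in% names(df) && has("race_white")) {
    df$white <- as.integer(cov("race_white"))
  }
  if (!"high_risk" %in% names(df)) {
    risk <- c("diabetes", "hypertension", "high_cholesterol",
              "heart_attack", "chf")
    present <- risk[vapply(risk, has, logical(1))]
    if (length(present) > 0) {
      df$high_risk <- as.integer(Reduce(`+`, lapply(present, cov)) > 0)
    }
  }
  if (!"depressed" %in% names(df) && has("depression")) {
    df$depressed <- as.integer(cov("depression"))
  }
  df
}

read_table_any <- function(path) {
  if (grepl("\\.dta$", path, ignore.case = TRUE)) {
    foreign::read.dta(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' @rdname read_sample
#' @param sample An `hf_sample`.
#' @export
write_sample <- function(sample, path) {
  stopifnot(inherits(sample, "hf_sample"))
  df <- as.data.frame(sample)
  # 17 significant digits: doubles survive the CSV round trip exactly
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write an analysis report to disk
#'
#' Emits the tidy machine-readable result set of a [run_analysis()] report:
#' `ate_gate.csv` (one row per outcome, analysis and subgroup),
#' `balance.csv`, `diagnostics.csv` (calibration tests),
#' `uptake_stages.csv` when the uptake decomposition was run, and
#' `manifest.json` (seed, parameters, retained covariates, drop counts).
#' Numeric values are written at full precision; re-running the same
#' analysis with the same seed reproduces the files byte for byte.
#'
#' @param report An `"hf_report"` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(report, out_dir) {
  stopifnot(inherits(report, "hf_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory %s", out_dir),
                  call. = FALSE)
  }
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     p, row.names = FALSE, quote = TRUE)
    paths <<- c(paths, p)
  }
  ate <- report$ate_gate
  if (!is.null(report$iv)) ate <- rbind(ate, report$iv)
  emit(ate, "ate_gate.csv")
  emit(report$balance, "balance.csv")
  emit(report$diagnostics, "diagnostics.csv")
  if (!is.null(report$uptake)) {
    emit(report$uptake$stage_gaps, "uptake_stages.csv")
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(report$manifest, mpath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, mpath)
  invisible(paths)
}

#' Serialize a forest to a JSON-lines file
#'
#' Writes one header record (format tag, forest type, dimensions,
#' hyperparameters) followed by one JSON record per tree (node arrays with
#' tree-local child indices, leaf payloads, in-bag households and
#' estimation-half assignments).  [read_forest()] reconstructs an ensemble
#' whose new-point predictions match the original exactly.
#'
#' @param object A fitted forest ([regression_forest()], [causal_forest()]
#'   or [instrumental_forest()]).
#' @param path Output file path.
#' @export
write_forest <- function(object, path) {
  flat <- object$forest
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- list(
    format = "hforest-trees-v1",
    type = flat$type, n_trees = flat$n_trees, n_rows = flat$n_rows,
    n_features = flat$n_features, n_households = flat$n_households,
    params = unclass(object$params))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  off <- flat$tree_offset
  ioff <- flat$inbag_offset
  eoff <- flat$est_offset
  for (b in seq_len(flat$n_trees)) {
    ndx <- (off[b] + 1):off[b + 1]
    rec <- list(
      var = flat$node_var[ndx],
      thr = flat$node_thr[ndx],
      left = ifelse(flat$node_left[ndx] >= 0,
                    flat$node_left[ndx] - off[b], -1L),
      right = ifelse(flat$node_right[ndx] >= 0,
                     flat$node_right[ndx] - off[b], -1L),
      depth = flat$node_depth[ndx],
      sumA = flat$leaf_sumA[ndx], sumB = flat$leaf_sumB[ndx],
      cnt = flat$leaf_cnt[ndx], value = flat$leaf_value[ndx],
      inherit = flat$leaf_inherit[ndx],
      inbag_hh = if (ioff[b + 1] > ioff[b]) {
        flat$inbag_hh[(ioff[b] + 1):ioff[b + 1]]
      } else {
        integer(0)
      },
      est_rows = if (eoff[b + 1] > eoff[b]) {
        flat$est_rows[(eoff[b] + 1):eoff[b + 1]]
      } else {
        integer(0)
      },
      est_leaf = if (eoff[b + 1] > eoff[b]) {
        flat$est_leaf[(eoff[b] + 1):eoff[b + 1]] - off[b]
      } else {
        integer(0)
      })
    writeLines(jsonlite::toJSON(rec, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_forest
#' @return `read_forest()` returns an object of class `"hf_forest_file"`
#'   supporting `predict(object, newdata)`.
#' @export
read_forest <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$format, "hforest-trees-v1")) {
    stop("not an hforest JSON-lines forest file", call. = FALSE)
  }
  flat <- list(
    n_rows = header$n_rows, n_features = header$n_features,
    n_households = header$n_households, type = header$type,
    n_trees = header$n_trees,
    node_var = integer(0), node_thr = numeric(0), node_left = integer(0),
    node_right = integer(0), node_depth = integer(0),
    leaf_sumA = numeric(0), leaf_sumB = numeric(0), leaf_cnt = numeric(0),
    leaf_value = numeric(0), leaf_inherit = integer(0),
    tree_offset = 0L, inbag_hh = integer(0), inbag_offset = 0L,
    est_rows = integer(0), est_leaf = integer(0), est_offset = 0L)
  for (b in seq_len(header$n_trees)) {
    rec <- jsonlite::fromJSON(lines[b + 1])
    base <- length(flat$node_var)
    flat$node_var <- c(flat$node_var, rec$var)
    flat$node_thr <- c(flat$node_thr, rec$thr)
    flat$node_left <- c(flat$node_left,
                        ifelse(rec$left >= 0, rec$left + base, -1L))
    flat$node_right <- c(flat$node_right,
                         ifelse(rec$right >= 0, rec$right + base, -1L))
    flat$node_depth <- c(flat$node_depth, rec$depth)
    flat$leaf_sumA <- c(flat$leaf_sumA, rec$sumA)
    flat$leaf_sumB <- c(flat$leaf_sumB, rec$sumB)
    flat$leaf_cnt <- c(flat$leaf_cnt, rec$cnt)
    flat$leaf_value <- c(flat$leaf_value, rec$value)
    flat$leaf_inherit <- c(flat$leaf_inherit, rec$inherit)
    flat$tree_offset <- c(flat$tree_offset, base + length(rec$var))
    flat$inbag_hh <- c(flat$inbag_hh, rec$inbag_hh)
    flat$inbag_offset <- c(flat$inbag_offset, length(flat$inbag_hh))
    flat$est_rows <- c(flat$est_rows, rec$est_rows)
    flat$est_leaf <- c(flat$est_leaf, rec$est_leaf + base)
    flat$est_offset <- c(flat$est_offset, length(flat$est_rows))
  }
  pars <- header$params
  if (length(pars$mtry) == 0) pars$mtry <- NULL
  structure(list(forest = flat, params = do.call(forest_params, pars)),
            class = "hf_forest_file")
}

#' @export
predict.hf_forest_file <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  res <- .hf_predict(object$forest, newdata)
  structure(res$value, n_trees_used = res$n_trees_used)
}
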