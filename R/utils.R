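# internal helpers: deterministic seed substreams, weighted moments,
# cluster-robust building blocks

# Deterministic 31-bit sub-seed for a named stage of a computation.  Every
# source of randomness in the package draws from its own substream so that
# adding a stage (a covariate, an outcome, a forest) never perturbs the draws
# of earlier stages.
hf_substream <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(((abs(as.numeric(seed)) %% 2147483647) * 69069 + h) %% 2147483647)
}

# run expr under a temporary RNG state seeded from (seed, key)
with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(hf_substream(seed, key))
  expr
}

weighted_mean <- function(x, w) sum(w * x) / sum(w)

# population-form weighted variance
weighted_var <- function(x, w) {
  m <- weighted_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# household-level sums of per-person values (for sandwich variances)
household_sums <- function(x, household) {
  as.numeric(rowsum(x, group = household, reorder = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
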