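# internal helpers shared across modules

# run expr with a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# logit with risk clamped away from 0/1 so margins stay finite
clamp_logit <- function(p, eps = 1e-12) {
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

# coerce outcome labels to an integer 0/1 vector
as_binary <- function(y, what = "labels") {
  if (is.factor(y)) y <- as.character(y)
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop(sprintf("%s must be binary 0/1", what), call. = FALSE)
  }
  as.integer(y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
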