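# Internal helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards so that seeded
#' package functions never perturb the user's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise a seed to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive `k` independent stage seeds from one master seed (kept < 2^31).
derive_seeds <- function(master_seed, k) {
  with_local_seed(master_seed, sample.int(.Machine$integer.max - 1L, k))
}

# Clamp probabilities away from 0/1 before logit transforms.
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_binary01 <- function(x) {
  v <- x[!is.na(x)]
  length(v) > 0L && all(v %in% c(0, 1))
}
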