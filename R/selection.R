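# Bootstrap-stepwise AIC consensus variable selection.
#
# The development procedure: stepwise AIC selection (bidirectional, from
# the intercept-only model) is repeated on bootstrap resamples of the
# cohort, and the consensus model keeps the predictors present in at
# least a threshold fraction (default 80%) of the replicate selections.

# logistic fit of y on the intercept plus X[, cols]; returns AIC or Inf
# on failure (the calling step treats Inf as "move unavailable")
.logistic_aic <- function(X, y, cols) {
  xm <- cbind(`(Intercept)` = 1, X[, cols, drop = FALSE])
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(xm, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$aic)) return(Inf)
  fit$aic
}

# core stepwise loop on a numeric design matrix
.stepwise_matrix <- function(X, y, candidates, direction = "both",
                             max_steps = 100L) {
  current <- if (direction == "backward") candidates else character(0)
  cur_aic <- .logistic_aic(X, y, current)
  log <- list()
  for (step in seq_len(max_steps)) {
    moves <- list()
    if (direction %in% c("both", "backward")) {
      for (p in current) {
        moves[[length(moves) + 1L]] <-
          list(type = "drop", predictor = p, set = setdiff(current, p))
      }
    }
    if (direction %in% c("both", "forward")) {
      for (p in setdiff(candidates, current)) {
        moves[[length(moves) + 1L]] <-
          list(type = "add", predictor = p, set = c(current, p))
      }
    }
    if (!length(moves)) break
    aics <- vapply(moves, function(m) .logistic_aic(X, y, m$set), numeric(1))
    if (all(!is.finite(aics))) break
    best <- min(aics)
    if (best >= cur_aic - 1e-8) break  # no strict improvement
    # ties within numerical tolerance: prefer the smaller model (drops),
    # then lexicographic predictor order — deterministic
    tied <- which(aics <= best + 1e-8)
    tied <- tied[order(vapply(moves[tied], function(m) m$type != "drop", logical(1)),
                       vapply(moves[tied], function(m) m$predictor, character(1)))]
    pick <- moves[[tied[1L]]]
    log[[length(log) + 1L]] <- data.frame(step = step, move = pick$type,
                                          predictor = pick$predictor,
                                          aic = aics[tied[1L]])
    current <- sort(pick$set)
    cur_aic <- aics[tied[1L]]
  }
  structure(sort(current), aic = cur_aic,
            steps = if (length(log)) do.call(rbind, log) else NULL)
}

#' Stepwise AIC predictor selection
#'
#' Repeatedly adds or drops a single predictor to minimise the Akaike
#' information criterion of the logistic model, stopping when no single
#' move improves AIC. Bidirectional search starts from the intercept-only
#' model; \code{"backward"} starts from the full candidate model. AIC
#' ties are broken deterministically: prefer the smaller model, then
#' lexicographic predictor order. A candidate move whose fit fails is
#' skipped.
#'
#' @param cohort preprocessed cohort data frame.
#' @param candidates nonempty character vector of candidate predictor
#'   columns.
#' @param outcome 0/1 outcome column name.
#' @param direction \code{"both"}, \code{"forward"} or \code{"backward"}.
#' @param max_steps guard on the number of accepted moves.
#' @return sorted character vector of selected predictors; attributes
#'   \code{aic} (final model AIC) and \code{steps} (move log).
#' @export
stepwise_aic <- function(cohort, candidates, outcome = "outcome",
                         direction = c("both", "forward", "backward"),
                         max_steps = 100L) {
  direction <- match.arg(direction)
  if (!length(candidates)) {
    y <- cohort[[outcome]]
    X0 <- matrix(numeric(0), length(y), 0, dimnames = list(NULL, character(0)))
    return(structure(character(0), aic = .logistic_aic(X0, y, character(0))))
  }
  miss <- setdiff(c(candidates, outcome), names(cohort))
  if (length(miss)) stopf("stepwise_aic: missing columns: %s", paste(miss, collapse = ", "))
  y <- cohort[[outcome]]
  if (length(unique(y)) < 2L) stopf("stepwise_aic: outcome has a single class")
  X <- as.matrix(cohort[candidates])
  if (anyNA(X)) stopf("stepwise_aic: missing predictor values; impute first")
  .stepwise_matrix(X, y, candidates, direction, max_steps)
}

#' Bootstrap consensus selection
#'
#' Draws \code{n_bootstrap} resamples of the cohort rows (with
#' replacement, seeded), runs \code{\link{stepwise_aic}} on each, and
#' retains the predictors selected in at least
#' \code{inclusion_threshold} of the converged replicates. Replicates
#' whose resample contains a single outcome class are skipped and counted
#' as non-converged; inclusion frequencies use the converged count as
#' denominator.
#'
#' @param cohort preprocessed cohort.
#' @param candidates candidate predictor columns.
#' @param n_bootstrap number of bootstrap replicates (default 2000).
#' @param inclusion_threshold consensus fraction in (0, 1] (default 0.80).
#' @param seed integer master seed; per-replicate seeds are derived from
#'   it so the whole run is reproducible.
#' @param outcome outcome column name.
#' @param direction stepwise direction.
#' @param max_steps stepwise step guard.
#' @param keep_sets retain each replicate's selected set in the result.
#' @return an object of class \code{selection_result}: inclusion
#'   frequencies, the consensus set, replicate bookkeeping.
#' @export
bootstrap_consensus <- function(cohort, candidates, n_bootstrap = 2000L,
                                inclusion_threshold = 0.80, seed = 1L,
                                outcome = "outcome",
                                direction = c("both", "forward", "backward"),
                                max_steps = 100L, keep_sets = FALSE) {
  direction <- match.arg(direction)
  if (n_bootstrap < 1) stopf("bootstrap_consensus: n_bootstrap must be >= 1")
  if (inclusion_threshold <= 0 || inclusion_threshold > 1) {
    stopf("bootstrap_consensus: inclusion_threshold must lie in (0, 1]")
  }
  y <- cohort[[outcome]]
  X <- as.matrix(cohort[candidates])
  if (anyNA(X)) stopf("bootstrap_consensus: missing predictor values; impute first")
  n <- nrow(X)
  seeds <- derive_seeds(seed, n_bootstrap)
  counts <- stats::setNames(integer(length(candidates)), candidates)
  n_converged <- 0L
  sets <- if (keep_sets) vector("list", n_bootstrap) else NULL
  n_skipped <- 0L
  for (b in seq_len(n_bootstrap)) {
    idx <- with_local_seed(seeds[b], sample.int(n, n, replace = TRUE))
    yb <- y[idx]
    if (length(unique(yb)) < 2L) { n_skipped <- n_skipped + 1L; next }
    sel <- .stepwise_matrix(X[idx, , drop = FALSE], yb, candidates,
                            direction, max_steps)
    n_converged <- n_converged + 1L
    counts[sel] <- counts[sel] + 1L
    if (keep_sets) sets[[b]] <- as.character(sel)
  }
  if (n_converged == 0L) stopf("bootstrap_consensus: no replicate converged")
  freq <- counts / n_converged
  structure(list(inclusion_frequency = freq,
                 consensus_set = names(freq)[freq >= inclusion_threshold],
                 n_converged_replicates = n_converged,
                 n_skipped_replicates = n_skipped,
                 n_bootstrap = n_bootstrap,
                 inclusion_threshold = inclusion_threshold,
                 per_replicate_sets = sets,
                 seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Bootstrap consensus selection: %d/%d replicates converged, threshold %.2f\n",
              x$n_converged_replicates, x$n_bootstrap, x$inclusion_threshold))
  f <- sort(x$inclusion_frequency, decreasing = TRUE)
  for (p in names(f)) {
    cat(sprintf("  %-24s %5.3f%s\n", p, f[[p]],
                if (p %in% x$consensus_set) "  *" else ""))
  }
  cat(sprintf("Consensus set (%d): %s\n", length(x$consensus_set),
              paste(x$consensus_set, collapse = ", ")))
  invisible(x)
}

#' Write the inclusion-frequency report
#'
#' @param result a \code{selection_result}.
#' @param path CSV path (predictor, frequency, selected).
#' @return the path, invisibly.
#' @export
write_selection_csv <- function(result, path) {
  df <- data.frame(predictor = names(result$inclusion_frequency),
                   frequency = unname(result$inclusion_frequency),
                   selected = names(result$inclusion_frequency) %in%
                     result$consensus_set)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Develop a triage model: consensus selection plus final fit
#'
#' Convenience wrapper running \code{\link{bootstrap_consensus}} and then
#' \code{\link{fit_triage_model}} on the consensus set over the full
#' cohort.
#'
#' @inheritParams bootstrap_consensus
#' @return list with elements \code{selection}
#'   (\code{selection_result}) and \code{model}
#'   (\code{\link{triage_model}}).
#' @export
develop_triage_model <- function(cohort, candidates, n_bootstrap = 2000L,
                                 inclusion_threshold = 0.80, seed = 1L,
                                 outcome = "outcome",
                                 direction = "both", max_steps = 100L) {
  sel <- bootstrap_consensus(cohort, candidates, n_bootstrap,
                             inclusion_threshold, seed, outcome,
                             direction, max_steps)
  if (!length(sel$consensus_set)) {
    stopf("develop_triage_model: consensus set is empty at threshold %.2f",
          inclusion_threshold)
  }
  model <- fit_triage_model(cohort, sel$consensus_set, outcome)
  list(selection = sel, model = model)
}
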