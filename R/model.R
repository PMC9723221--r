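#' Construct a triage model object
#'
#' The container for a fitted (or published) logistic triage model:
#' intercept, named coefficients on the transformed-predictor scale,
#' standard errors, odds ratios with Wald 95% confidence intervals, and
#' fit metadata. \code{sqrt_age} and \code{vs_spo2} refer to the square
#' root of age in months and the virtual-shunt transform of SpO2; raw
#' cohorts are transformed automatically at prediction time.
#'
#' @param intercept numeric intercept on the logit scale.
#' @param coefficients named numeric vector of predictor coefficients.
#' @param se named numeric vector of standard errors (NA when unknown).
#' @param n_obs number of observations used in the fit.
#' @param aic model AIC (NA when not fitted here).
#' @param vcov optional variance-covariance matrix.
#' @param separation logical; TRUE when separation forced a ridge refit.
#' @param thresholds numeric length-2 vector \code{c(low, high)} of default
#'   risk thresholds, or NULL.
#' @param source character label ("fitted", "published", ...).
#' @return an object of class \code{triage_model}.
#' @export
triage_model <- function(intercept, coefficients, se = NULL, n_obs = NA_integer_,
                         aic = NA_real_, vcov = NULL, separation = FALSE,
                         thresholds = NULL, source = "fitted") {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)))
  if (is.null(se)) se <- stats::setNames(rep(NA_real_, length(coefficients)),
                                         names(coefficients))
  or <- odds_ratio(coefficients, se)
  structure(list(intercept = intercept,
                 coefficients = coefficients,
                 se = se,
                 odds_ratios = or,
                 n_obs = n_obs,
                 aic = aic,
                 vcov = vcov,
                 separation = isTRUE(separation),
                 thresholds = thresholds,
                 source = source),
            class = "triage_model")
}

#' Odds ratios with Wald confidence intervals
#'
#' \code{exp(coefficient)} with 95% interval
#' \code{exp(coefficient +/- 1.96 se)}; interval is NA when the standard
#' error is unknown.
#'
#' @param coefficients named numeric vector of logistic coefficients.
#' @param se matching standard errors (optional).
#' @return data frame with columns \code{predictor}, \code{or},
#'   \code{or_low}, \code{or_high}.
#' @examples
#' odds_ratio(c(temperature_c = 0.819))  # 2.27
#' @export
odds_ratio <- function(coefficients, se = NULL) {
  if (is.null(names(coefficients))) {
    names(coefficients) <- paste0("x", seq_along(coefficients))
  }
  if (is.null(se)) se <- rep(NA_real_, length(coefficients))
  z <- stats::qnorm(0.975)
  data.frame(predictor = names(coefficients),
             or = exp(unname(coefficients)),
             or_low = exp(unname(coefficients) - z * se),
             or_high = exp(unname(coefficients) + z * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the final logistic triage model
#'
#' Maximum-likelihood logistic regression of the composite admission
#' outcome on a consensus predictor set, on the full preprocessed cohort.
#' When the fit shows (quasi-)separation — non-convergence or fitted
#' probabilities collapsing to 0/1 — the model is refit with a small ridge
#' penalty and flagged.
#'
#' @param cohort preprocessed cohort (see \code{\link{preprocess_cohort}}).
#' @param predictors character vector of predictor columns (nonempty).
#' @param outcome name of the 0/1 outcome column.
#' @param ridge_lambda penalty used by the separation fallback.
#' @return a \code{\link{triage_model}}.
#' @export
fit_triage_model <- function(cohort, predictors, outcome = "outcome",
                             ridge_lambda = 1e-3) {
  if (!length(predictors)) stopf("fit_triage_model: empty predictor set")
  miss <- setdiff(c(predictors, outcome), names(cohort))
  if (length(miss)) stopf("fit_triage_model: missing columns: %s", paste(miss, collapse = ", "))
  y <- cohort[[outcome]]
  if (length(unique(y)) < 2L) stopf("fit_triage_model: outcome has a single class")
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- suppressWarnings(stats::glm(fml, data = cohort, family = stats::binomial()))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # separation shows as non-convergence, runaway coefficients or
  # exploding Wald standard errors (tiny fitted risks alone are normal)
  separated <- !fit$converged || anyNA(cf) ||
    any(abs(cf) > 50) || any(!is.finite(se)) || any(se > 100)
  if (!separated) {
    return(triage_model(intercept = unname(cf["(Intercept)"]),
                        coefficients = cf[predictors],
                        se = se[predictors],
                        n_obs = nrow(cohort), aic = stats::AIC(fit),
                        vcov = stats::vcov(fit),
                        thresholds = NULL, source = "fitted"))
  }
  # ridge fallback under separation: finite coefficients, no Wald SEs
  x <- as.matrix(cohort[predictors])
  pf <- rep(1, ncol(x))
  if (ncol(x) == 1L) {  # glmnet requires >= 2 columns; pad with an unpenalised zero column
    x <- cbind(x, `..pad` = 0)
    pf <- c(1, 0)
  }
  rf <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = ridge_lambda, standardize = FALSE,
                       penalty.factor = pf)
  cf <- as.numeric(stats::coef(rf))
  names(cf) <- rownames(stats::coef(rf))
  triage_model(intercept = unname(cf["(Intercept)"]),
               coefficients = cf[predictors],
               se = stats::setNames(rep(NA_real_, length(predictors)), predictors),
               n_obs = nrow(cohort), aic = NA_real_, separation = TRUE,
               thresholds = NULL, source = "fitted-ridge")
}

#' The published nine-predictor triage model
#'
#' The deployed triage score as a fixed, exactly testable object:
#' logit(p) = -32.888 + 0.252 sqrt(age months) + 0.016 heart rate +
#' 0.819 temperature - 0.022 MUAC + 0.048 virtual-shunt SpO2 +
#' 1.793 parent concern + 1.012 difficulty breathing + 1.814 oedema +
#' 1.506 pallor, with risk thresholds 0.08 (non-urgent boundary) and 0.40
#' (emergency boundary). Age enters in months under the square root.
#' These constants are immutable; the object carries the published OR
#' confidence intervals for reporting.
#'
#' @return a \code{\link{triage_model}} with \code{source = "published"}.
#' @examples
#' m <- published_triage_model()
#' exp(coef(m)[["temperature_c"]])  # odds ratio 2.27 per degree C
#' @export
published_triage_model <- function() {
  cf <- c(sqrt_age = 0.252, heart_rate_bpm = 0.016, temperature_c = 0.819,
          muac_mm = -0.022, vs_spo2 = 0.048, parent_concern = 1.793,
          difficulty_breathing = 1.012, oedema = 1.814, pallor = 1.506)
  m <- triage_model(intercept = -32.888, coefficients = cf,
                    n_obs = 1612L, thresholds = c(low = 0.08, high = 0.40),
                    source = "published")
  # published 95% CIs on the odds-ratio scale
  ci <- matrix(c(1.18, 1.40,   # sqrt_age
                 1.01, 1.02,   # heart_rate_bpm
                 1.92, 2.69,   # temperature_c
                 0.97, 0.98,   # muac_mm
                 1.02, 1.07,   # vs_spo2
                 3.79, 9.63,   # parent_concern
                 1.97, 3.84,   # difficulty_breathing
                 2.44, 10.76,  # oedema
                 2.69, 7.59),  # pallor
               ncol = 2, byrow = TRUE)
  m$odds_ratios$or_low <- ci[, 1]
  m$odds_ratios$or_high <- ci[, 2]
  m
}

#' @export
coef.triage_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict admission risk from a triage model
#'
#' Computes the linear predictor on the model's transformed scale and
#' applies the logistic function. Raw cohorts (with \code{age_months} /
#' \code{spo2_pct} but without \code{sqrt_age} / \code{vs_spo2}) are
#' transformed on the fly.
#'
#' @param object a \code{\link{triage_model}}.
#' @param newdata data frame of predictor columns.
#' @param type \code{"response"} (probability), \code{"link"} (logit), or
#'   \code{"category"} (triage category at the model's thresholds).
#' @param thresholds optional \code{c(low, high)} overriding the model's
#'   thresholds for \code{type = "category"}.
#' @param ... unused.
#' @return numeric vector, or factor for \code{type = "category"}.
#' @export
predict.triage_model <- function(object, newdata,
                                 type = c("response", "link", "category"),
                                 thresholds = NULL, ...) {
  type <- match.arg(type)
  need <- names(object$coefficients)
  if (!all(need %in% names(newdata)) &&
      all(c("age_months", "spo2_pct") %in% names(newdata))) {
    newdata <- transform_predictors(newdata)
  }
  miss <- setdiff(need, names(newdata))
  if (length(miss)) stopf("predict.triage_model: missing predictors: %s",
                          paste(miss, collapse = ", "))
  x <- as.matrix(newdata[need])
  if (anyNA(x)) stopf("predict.triage_model: missing predictor values; impute first")
  lp <- drop(object$intercept + x %*% object$coefficients)
  if (type == "link") return(lp)
  p <- stats::plogis(lp)
  if (type == "response") return(p)
  th <- thresholds %||% object$thresholds
  if (is.null(th)) stopf("predict.triage_model: no thresholds available for categorisation")
  categorize(p, low = th[[1]], high = th[[2]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.triage_model <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic triage model (%s), %s predictors\n",
              x$source, length(x$coefficients)))
  cat(sprintf("  logit(p) = %.3f %s\n", x$intercept,
              paste(sprintf("%+0.3f*%s", x$coefficients, names(x$coefficients)),
                    collapse = " ")))
  if (!is.na(x$aic)) cat(sprintf("  n = %d, AIC = %.1f\n", x$n_obs, x$aic))
  if (x$separation) cat("  note: separation detected; ridge-penalised fit\n")
  invisible(x)
}

#' @export
summary.triage_model <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(estimate = object$coefficients,
                    se = object$se,
                    p_value = 2 * stats::pnorm(-abs(z)),
                    or = object$odds_ratios$or,
                    or_low = object$odds_ratios$or_low,
                    or_high = object$odds_ratios$or_high)
  res <- list(model = object, table = tab)
  class(res) <- "summary.triage_model"
  res
}

#' @export
print.summary.triage_model <- function(x, digits = 3, ...) {
  print(x$model)
  cat(sprintf("  intercept: %.3f\n", x$model$intercept))
  print(round(x$table, digits))
  invisible(x)
}

#' Simulate outcomes from a triage model
#'
#' Bernoulli draws at the model's predicted risks, one column per
#' replicate.
#'
#' @param object a \code{\link{triage_model}}.
#' @param nsim number of replicate outcome vectors.
#' @param seed integer seed.
#' @param newdata cohort to predict on.
#' @param ... unused.
#' @return data frame of 0/1 outcomes, \code{nsim} columns.
#' @export
simulate.triage_model <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  p <- predict(object, newdata, type = "response")
  draw <- function() stats::rbinom(length(p), 1L, p)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw(), simplify = FALSE)
  } else {
    with_local_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  }
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Residuals of a triage model on a cohort
#'
#' @param object a \code{\link{triage_model}}.
#' @param cohort preprocessed cohort carrying the outcome column.
#' @param outcome outcome column name.
#' @param type \code{"response"} (y - p) or \code{"pearson"}.
#' @param ... unused.
#' @return numeric vector of residuals.
#' @export
residuals.triage_model <- function(object, cohort, outcome = "outcome",
                                   type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  p <- predict(object, cohort, type = "response")
  r <- cohort[[outcome]] - p
  if (type == "pearson") r <- r / sqrt(p * (1 - p))
  r
}

#' Write / read a triage model as JSON
#'
#' The JSON document (predictors, intercept, coefficients, SEs, OR CIs,
#' thresholds, fit metadata) is the interchange format linking model
#' development to evaluation, stratification and scoring; the published
#' model exports through the same format.
#'
#' @param model a \code{\link{triage_model}}.
#' @param path file path.
#' @return \code{write_model_json} returns the path invisibly;
#'   \code{read_model_json} returns a \code{triage_model}.
#' @export
write_model_json <- function(model, path) {
  doc <- list(class = "triage_model",
              source = model$source,
              intercept = model$intercept,
              predictors = names(model$coefficients),
              coefficients = as.list(model$coefficients),
              se = as.list(model$se),
              odds_ratios = model$odds_ratios,
              n_obs = model$n_obs,
              aic = model$aic,
              separation = model$separation,
              thresholds = if (is.null(model$thresholds)) NULL else
                as.list(model$thresholds))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$class) || doc$class != "triage_model") {
    stopf("read_model_json: %s is not a triage model document", path)
  }
  th <- if (is.null(doc$thresholds)) NULL else unlist(doc$thresholds)
  pick <- function(field) {
    vapply(doc$predictors, function(p) {
      v <- field[[p]]
      if (is.null(v) || (length(v) == 1L && is.na(v))) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  m <- triage_model(intercept = doc$intercept,
                    coefficients = pick(doc$coefficients),
                    se = pick(doc$se),
                    n_obs = doc$n_obs,
                    aic = if (is.null(doc$aic)) NA_real_ else doc$aic,
                    separation = isTRUE(doc$separation),
                    thresholds = th, source = doc$source)
  m$odds_ratios <- doc$odds_ratios
  m
}
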