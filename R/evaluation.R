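# Cross-validated discrimination, bootstrap uncertainty and calibration.

#' Rank (Mann-Whitney) AUROC
#'
#' Probability that a randomly chosen positive receives a higher risk
#' than a randomly chosen negative, ties counted one half — identical to
#' the area under the empirical ROC curve.
#'
#' @param risks numeric risk scores.
#' @param outcomes 0/1 outcomes, both classes present.
#' @return AUROC in [0, 1].
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auroc <- function(risks, outcomes) {
  stopifnot(length(risks) == length(outcomes))
  keep <- !is.na(risks) & !is.na(outcomes)
  risks <- risks[keep]; outcomes <- outcomes[keep]
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) stopf("auroc: both outcome classes must be present")
  r <- rank(risks)
  n1 <- as.numeric(n1); n0 <- as.numeric(n0)
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' @param risks numeric risk scores.
#' @param outcomes 0/1 outcomes.
#' @return data frame \code{threshold}, \code{fpr}, \code{tpr}, ordered
#'   by increasing false-positive rate; positivity is risk > threshold.
#' @export
roc_curve <- function(risks, outcomes) {
  th <- c(Inf, sort(unique(risks), decreasing = TRUE), -Inf)
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  tpr <- vapply(th, function(t) sum(risks > t & outcomes == 1) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(risks > t & outcomes == 0) / n0, numeric(1))
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

#' Stratified out-of-fold predicted risks
#'
#' Assigns each row to one of \code{n_folds} folds (stratified on the
#' outcome so every training fold sees both classes), fits the logistic
#' model on the complement of each fold, and returns the single
#' out-of-fold predicted risk per row. Pooling these predictions gives
#' the cross-validated AUROC.
#'
#' @param cohort preprocessed cohort.
#' @param predictors predictor columns of the model.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param outcome outcome column name.
#' @param stratified stratify fold assignment on the outcome.
#' @return numeric vector of out-of-fold risks, aligned with the cohort
#'   rows; attribute \code{fold} carries the assignment.
#' @export
cross_validated_predictions <- function(cohort, predictors, n_folds = 10L,
                                        seed = 1L, outcome = "outcome",
                                        stratified = TRUE) {
  if (n_folds < 2) stopf("cross_validated_predictions: n_folds must be >= 2")
  y <- cohort[[outcome]]
  n <- nrow(cohort)
  fold <- integer(n)
  with_local_seed(seed, {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold <- sample(rep_len(seq_len(n_folds), n))
    }
  })
  risks <- rep(NA_real_, n)
  for (k in seq_len(n_folds)) {
    train <- cohort[fold != k, , drop = FALSE]
    if (length(unique(train[[outcome]])) < 2L) {
      stopf("cross_validated_predictions: training fold %d has a single outcome class; use a larger cohort", k)
    }
    m <- fit_triage_model(train, predictors, outcome)
    risks[fold == k] <- predict(m, cohort[fold == k, , drop = FALSE],
                                type = "response")
  }
  attr(risks, "fold") <- fold
  risks
}

#' Threshold classification metrics
#'
#' Confusion-matrix metrics with the positivity convention risk >
#' threshold: sensitivity, specificity, PPV, NPV, LR+ = sens/(1 - spec),
#' LR- = (1 - sens)/spec.
#'
#' @param risks numeric risks.
#' @param outcomes 0/1 outcomes.
#' @param threshold classification boundary.
#' @return named numeric vector (tp, fp, tn, fn included).
#' @export
classification_metrics <- function(risks, outcomes, threshold) {
  pos <- risks > threshold
  tp <- sum(pos & outcomes == 1); fp <- sum(pos & outcomes == 0)
  fn <- sum(!pos & outcomes == 1); tn <- sum(!pos & outcomes == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  c(tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    lr_pos = if (!is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_,
    lr_neg = if (!is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_)
}

#' Bootstrap confidence interval for a threshold metric or the AUROC
#'
#' Resamples (risk, outcome) pairs with replacement \code{B} times and
#' reports the plug-in point estimate, percentile 95% interval and
#' bootstrap standard error. Replicates on which the metric is undefined
#' (a resample missing one class) are skipped and counted.
#'
#' @param risks numeric risks.
#' @param outcomes 0/1 outcomes.
#' @param metric one of \code{"auroc"}, \code{"sensitivity"},
#'   \code{"specificity"}, \code{"ppv"}, \code{"npv"}, \code{"lr_pos"},
#'   \code{"lr_neg"}.
#' @param threshold classification boundary (ignored for AUROC).
#' @param B number of bootstrap replicates (>= 100 for a CI).
#' @param seed integer seed.
#' @return list \code{point}, \code{low}, \code{high}, \code{se},
#'   \code{n_skipped}.
#' @export
bootstrap_metric_ci <- function(risks, outcomes, metric = "auroc",
                                threshold = NULL, B = 2000L, seed = 1L) {
  if (B < 100) stopf("bootstrap_metric_ci: B must be >= 100 for interval output")
  eval_metric <- function(r, y) {
    if (length(unique(y)) < 2L) return(NA_real_)
    if (metric == "auroc") return(auroc(r, y))
    m <- classification_metrics(r, y, threshold)
    if (!metric %in% names(m)) stopf("bootstrap_metric_ci: unknown metric '%s'", metric)
    unname(m[[metric]])
  }
  point <- eval_metric(risks, outcomes)
  n <- length(risks)
  seeds <- derive_seeds(seed, 1L)
  stats_b <- with_local_seed(seeds[1L], {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      eval_metric(risks[idx], outcomes[idx])
    }, numeric(1))
  })
  ok <- stats_b[is.finite(stats_b)]
  list(point = point,
       low = unname(stats::quantile(ok, 0.025, na.rm = TRUE)),
       high = unname(stats::quantile(ok, 0.975, na.rm = TRUE)),
       se = stats::sd(ok),
       n_skipped = B - length(ok))
}

#' Calibration curve with bootstrap bias correction
#'
#' Bins predicted risks into equal-count bins and compares the mean
#' predicted risk to the observed outcome frequency per bin. A logistic
#' recalibration fit (outcome on logit of risk) yields the calibration
#' slope and intercept: slope 1 and intercept 0 indicate perfect
#' calibration. The bias-corrected curve refits the recalibration model
#' on each bootstrap resample, evaluates it on the original bin risks,
#' and averages over replicates.
#'
#' @param risks predicted risks in (0, 1).
#' @param outcomes 0/1 outcomes.
#' @param n_bins number of equal-count bins (>= 2; bins sharing a
#'   boundary value are merged).
#' @param B number of bias-correction bootstrap replicates (default
#'   1000); 0 disables the corrected curve.
#' @param seed integer seed.
#' @return object of class \code{calibration_curve}: data frame
#'   \code{curve} (\code{bin_mid}, \code{predicted}, \code{observed},
#'   \code{corrected}, \code{n}), \code{slope}, \code{intercept}.
#' @export
calibration_curve <- function(risks, outcomes, n_bins = 10L, B = 1000L,
                              seed = 1L) {
  if (n_bins < 2) stopf("calibration_curve: n_bins must be >= 2")
  lp <- stats::qlogis(clamp_prob(risks))
  breaks <- unique(stats::quantile(risks, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3L) {
    bin <- factor(rep(1L, length(risks)))  # constant risk: single bin
  } else {
    bin <- cut(risks, breaks, include.lowest = TRUE)
  }
  curve <- data.frame(
    bin_mid = as.numeric(tapply(risks, bin, mean)),
    predicted = as.numeric(tapply(risks, bin, mean)),
    observed = as.numeric(tapply(outcomes, bin, mean)),
    n = as.integer(tapply(outcomes, bin, length)))
  recal <- suppressWarnings(
    stats::glm(outcomes ~ lp, family = stats::binomial()))
  slope <- unname(stats::coef(recal)[2L])
  intercept <- unname(stats::coef(recal)[1L])
  corrected <- rep(NA_real_, nrow(curve))
  if (B > 0) {
    n <- length(risks)
    lp_mid <- stats::qlogis(clamp_prob(curve$bin_mid))
    seeds <- derive_seeds(seed, 1L)
    acc <- with_local_seed(seeds[1L], {
      vapply(seq_len(B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- outcomes[idx]
        if (length(unique(yb)) < 2L) return(rep(NA_real_, nrow(curve)))
        fb <- suppressWarnings(stats::glm(yb ~ lp[idx],
                                          family = stats::binomial()))
        stats::plogis(stats::coef(fb)[1L] + stats::coef(fb)[2L] * lp_mid)
      }, numeric(nrow(curve)))
    })
    if (is.null(dim(acc))) acc <- matrix(acc, nrow = nrow(curve))
    corrected <- rowMeans(acc, na.rm = TRUE)
  }
  curve$corrected <- corrected
  structure(list(curve = curve, slope = slope, intercept = intercept,
                 n_bins = nlevels(bin)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: slope %.3f, intercept %.3f over %d bins\n",
              x$slope, x$intercept, x$n_bins))
  print(round(x$curve, 4))
  invisible(x)
}

#' Evaluate a predictor set on a cohort
#'
#' The full evaluation stage: stratified 10-fold cross-validated
#' out-of-fold risks pooled into an AUROC with percentile bootstrap CI,
#' per-fold AUROCs, threshold metrics with CIs at any requested
#' boundaries, and the bias-corrected calibration curve. An optional
#' repeated 80/20 Monte-Carlo split estimate is reported alongside when
#' \code{n_split_repeats > 0}.
#'
#' @param cohort preprocessed cohort.
#' @param predictors predictor columns.
#' @param thresholds numeric vector of classification boundaries to
#'   report metrics at (may be empty).
#' @param n_folds folds for cross-validation (default 10).
#' @param n_bootstrap_metrics bootstrap replicates for metric CIs
#'   (default 2000).
#' @param n_bootstrap_calibration replicates for calibration bias
#'   correction (default 1000).
#' @param n_split_repeats repeated 80/20 train/validation splits
#'   (0 disables).
#' @param test_fraction validation fraction of the split mode.
#' @param seed integer master seed.
#' @param outcome outcome column name.
#' @return object of class \code{triage_evaluation}.
#' @export
evaluate_model <- function(cohort, predictors, thresholds = numeric(0),
                           n_folds = 10L, n_bootstrap_metrics = 2000L,
                           n_bootstrap_calibration = 1000L,
                           n_split_repeats = 0L, test_fraction = 0.20,
                           seed = 1L, outcome = "outcome") {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stopf("evaluate_model: test_fraction must lie in (0, 1)")
  }
  seeds <- derive_seeds(seed, 4L)
  y <- cohort[[outcome]]
  risks <- cross_validated_predictions(cohort, predictors, n_folds,
                                       seed = seeds[1L], outcome = outcome)
  fold <- attr(risks, "fold")
  pooled <- bootstrap_metric_ci(risks, y, "auroc", B = n_bootstrap_metrics,
                                seed = seeds[2L])
  per_fold <- vapply(seq_len(n_folds), function(k) {
    idx <- fold == k
    if (length(unique(y[idx])) < 2L) return(NA_real_)
    auroc(risks[idx], y[idx])
  }, numeric(1))
  thr_metrics <- lapply(thresholds, function(t) {
    pt <- classification_metrics(risks, y, t)
    cis <- lapply(c("sensitivity", "specificity", "ppv", "npv",
                    "lr_pos", "lr_neg"), function(m) {
      bootstrap_metric_ci(risks, y, m, threshold = t,
                          B = n_bootstrap_metrics, seed = seeds[3L])
    })
    names(cis) <- c("sensitivity", "specificity", "ppv", "npv",
                    "lr_pos", "lr_neg")
    list(threshold = t, point = pt, ci = cis)
  })
  calib <- calibration_curve(risks, y, B = n_bootstrap_calibration,
                             seed = seeds[4L])
  split <- NULL
  if (n_split_repeats > 0) {
    split_seeds <- derive_seeds(seeds[1L] + 1L, n_split_repeats)
    aucs <- vapply(seq_len(n_split_repeats), function(r) {
      idx <- with_local_seed(split_seeds[r], {
        test <- logical(nrow(cohort))
        for (cls in unique(y)) {
          w <- which(y == cls)
          test[sample(w, max(1L, round(test_fraction * length(w))))] <- TRUE
        }
        test
      })
      m <- fit_triage_model(cohort[!idx, , drop = FALSE], predictors, outcome)
      auroc(predict(m, cohort[idx, , drop = FALSE], type = "response"), y[idx])
    }, numeric(1))
    split <- list(mean_auroc = mean(aucs), per_repeat = aucs,
                  test_fraction = test_fraction)
  }
  structure(list(pooled_auroc = pooled,
                 per_fold_auroc = per_fold,
                 oof_risks = as.numeric(risks),
                 fold = fold,
                 threshold_metrics = thr_metrics,
                 calibration = calib,
                 split = split,
                 n = nrow(cohort),
                 predictors = predictors,
                 seed = seed),
            class = "triage_evaluation")
}

#' @export
print.triage_evaluation <- function(x, ...) {
  cat(sprintf("Cross-validated evaluation (n = %d, %d predictors)\n",
              x$n, length(x$predictors)))
  cat(sprintf("  pooled AUROC %.3f (95%% CI %.3f, %.3f)\n",
              x$pooled_auroc$point, x$pooled_auroc$low, x$pooled_auroc$high))
  cat(sprintf("  per-fold AUROC: %s\n",
              paste(sprintf("%.3f", x$per_fold_auroc), collapse = " ")))
  cat(sprintf("  calibration slope %.3f, intercept %.3f\n",
              x$calibration$slope, x$calibration$intercept))
  for (tm in x$threshold_metrics) {
    cat(sprintf("  threshold %.3f: sens %.3f spec %.3f ppv %.3f npv %.3f\n",
                tm$threshold, tm$point[["sensitivity"]],
                tm$point[["specificity"]], tm$point[["ppv"]],
                tm$point[["npv"]]))
  }
  if (!is.null(x$split)) {
    cat(sprintf("  repeated %.0f/%.0f split AUROC (mean of %d): %.3f\n",
                100 * (1 - x$split$test_fraction),
                100 * x$split$test_fraction,
                length(x$split$per_repeat), x$split$mean_auroc))
  }
  invisible(x)
}

#' Plot evaluation: ROC and calibration
#'
#' Base-graphics panel with the pooled out-of-fold ROC curve and the
#' calibration plot (identity line = perfect calibration).
#'
#' @param x a \code{triage_evaluation}.
#' @param outcomes 0/1 outcomes aligned with the evaluated cohort.
#' @param ... passed to \code{plot}.
#' @export
plot.triage_evaluation <- function(x, outcomes, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  rc <- roc_curve(x$oof_risks, outcomes)
  plot(rc$fpr, rc$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("ROC (AUROC %.2f)", x$pooled_auroc$point), ...)
  graphics::abline(0, 1, lty = 3)
  cc <- x$calibration$curve
  plot(cc$predicted, cc$observed, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Predicted risk", ylab = "Observed frequency",
       main = "Calibration", type = "b")
  if (!all(is.na(cc$corrected))) {
    graphics::lines(cc$predicted, cc$corrected, lty = 2, col = "grey40")
  }
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Write evaluation artifacts
#'
#' JSON report plus plain CSV curves: the ROC as (threshold, fpr, tpr)
#' and the calibration curve as (bin_mid, predicted, observed,
#' corrected).
#'
#' @param evaluation a \code{triage_evaluation}.
#' @param outcomes 0/1 outcomes for the ROC curve CSV.
#' @param json_path,roc_path,calibration_path output paths (NULL skips).
#' @return \code{json_path}, invisibly.
#' @export
write_evaluation <- function(evaluation, outcomes, json_path,
                             roc_path = NULL, calibration_path = NULL) {
  doc <- list(class = "triage_evaluation",
              n = evaluation$n,
              predictors = evaluation$predictors,
              pooled_auroc = evaluation$pooled_auroc,
              per_fold_auroc = evaluation$per_fold_auroc,
              threshold_metrics = evaluation$threshold_metrics,
              calibration = list(slope = evaluation$calibration$slope,
                                 intercept = evaluation$calibration$intercept,
                                 curve = evaluation$calibration$curve),
              split = evaluation$split)
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  if (!is.null(roc_path)) {
    utils::write.csv(roc_curve(evaluation$oof_risks, outcomes), roc_path,
                     row.names = FALSE)
  }
  if (!is.null(calibration_path)) {
    utils::write.csv(evaluation$calibration$curve, calibration_path,
                     row.names = FALSE)
  }
  invisible(json_path)
}
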