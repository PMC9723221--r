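# Dual-threshold three-category risk stratification.

#' Select low/high risk thresholds from sensitivity/specificity targets
#'
#' Scans the sorted unique risks as candidate boundaries with the
#' positivity convention risk > threshold. The low (non-urgent) boundary
#' is the LARGEST candidate whose sensitivity still meets
#' \code{target_sensitivity} — maximising specificity subject to the
#' sensitivity floor; the high (emergency) boundary is the SMALLEST
#' candidate whose specificity meets \code{target_specificity} —
#' maximising sensitivity subject to the specificity floor. When the two
#' cross (\code{low >= high}) the stratification degenerates to two
#' categories: both boundaries are set to the low candidate and a warning
#' is raised rather than failing.
#'
#' @param risks numeric risks.
#' @param outcomes 0/1 outcomes, both classes present.
#' @param target_sensitivity sensitivity floor at the low boundary
#'   (default 0.90).
#' @param target_specificity specificity floor at the high boundary
#'   (default 0.90).
#' @return list of class \code{threshold_pair}: \code{low}, \code{high},
#'   targets, achieved sensitivity/specificity at each boundary,
#'   \code{degenerate} flag.
#' @export
select_thresholds <- function(risks, outcomes, target_sensitivity = 0.90,
                              target_specificity = 0.90) {
  if (target_sensitivity < 0 || target_sensitivity >= 1 ||
      target_specificity < 0 || target_specificity >= 1) {
    stopf("select_thresholds: targets must lie in [0, 1)")
  }
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) stopf("select_thresholds: both outcome classes must be present")
  cand <- sort(unique(risks))
  sens <- vapply(cand, function(t) sum(risks > t & outcomes == 1) / n1, numeric(1))
  spec <- vapply(cand, function(t) sum(risks <= t & outcomes == 0) / n0, numeric(1))
  ok_lo <- which(sens >= target_sensitivity)
  if (!length(ok_lo)) {
    stopf("select_thresholds: sensitivity target %.2f unattainable; maximum achievable is %.3f",
          target_sensitivity, max(sens))
  }
  ok_hi <- which(spec >= target_specificity)
  if (!length(ok_hi)) {
    stopf("select_thresholds: specificity target %.2f unattainable; maximum achievable is %.3f",
          target_specificity, max(spec))
  }
  lo_i <- max(ok_lo); hi_i <- min(ok_hi)
  degenerate <- cand[lo_i] >= cand[hi_i]
  if (degenerate) {
    warnf("select_thresholds: low boundary %.4f >= high boundary %.4f; collapsing to a two-category stratification",
          cand[lo_i], cand[hi_i])
    hi_i <- lo_i
  }
  structure(list(low = cand[lo_i], high = cand[hi_i],
                 target_sensitivity = target_sensitivity,
                 target_specificity = target_specificity,
                 achieved_sensitivity_low = sens[lo_i],
                 achieved_specificity_high = spec[hi_i],
                 degenerate = degenerate),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("Risk thresholds: low %.4f (sens %.3f), high %.4f (spec %.3f)%s\n",
              x$low, x$achieved_sensitivity_low, x$high,
              x$achieved_specificity_high,
              if (x$degenerate) " [degenerate: two categories]" else ""))
  invisible(x)
}

#' Assign triage categories
#'
#' Boundaries are inclusive on the left: risk <= low is non-urgent,
#' low < risk <= high is priority, risk > high is emergency.
#'
#' @param risk numeric risks in [0, 1].
#' @param low,high risk boundaries, or a \code{threshold_pair} as
#'   \code{low}.
#' @return factor with levels non-urgent, priority, emergency.
#' @examples
#' categorize(c(0.08, 0.40, 0.401), 0.08, 0.40)
#' @export
categorize <- function(risk, low, high = NULL) {
  if (inherits(low, "threshold_pair")) { high <- low$high; low <- low$low }
  if (any(risk < 0 | risk > 1, na.rm = TRUE)) stopf("categorize: risks must lie in [0, 1]")
  out <- ifelse(risk > high, "emergency",
                ifelse(risk > low, "priority", "non-urgent"))
  factor(out, levels = c("non-urgent", "priority", "emergency"))
}

#' Three-category risk stratification report
#'
#' Tallies each triage category (participants, positive outcomes, stay
#' durations, readmissions, mortality when available) and computes
#' boundary classification metrics by treating every category at or
#' above a boundary as test-positive — i.e. at the low boundary,
#' priority-or-emergency is positive; at the high boundary, emergency is
#' positive. True:false positive counts are reported per boundary, and
#' metrics recomputed from those counts equal the reported metrics
#' exactly. Percentile bootstrap CIs are attached when \code{B > 0}.
#'
#' @param cohort cohort data frame with the derived \code{outcome} and
#'   disposition columns.
#' @param risks predicted risks aligned with the cohort rows.
#' @param thresholds a \code{threshold_pair} or numeric \code{c(low, high)}.
#' @param B bootstrap replicates for metric CIs (0 disables).
#' @param seed integer seed for the bootstrap.
#' @return object of class \code{stratification_report}.
#' @export
build_report <- function(cohort, risks, thresholds, B = 0L, seed = 1L) {
  if (length(risks) != nrow(cohort)) stopf("build_report: risks not aligned with cohort rows")
  if (inherits(thresholds, "threshold_pair")) {
    low <- thresholds$low; high <- thresholds$high
  } else {
    low <- thresholds[[1]]; high <- thresholds[[2]]
  }
  y <- cohort$outcome
  if (is.null(y)) stopf("build_report: cohort lacks a derived outcome column")
  cat3 <- categorize(risks, low, high)
  lev <- levels(cat3)
  tab_n <- table(cat3)
  tally <- function(flag) as.integer(tapply(flag, cat3, sum, default = 0L))
  adm <- cohort$admitted == 1
  stay <- cohort$length_of_stay_hours
  counts <- data.frame(
    category = lev,
    participants = as.integer(tab_n),
    participants_pct = as.numeric(tab_n) / nrow(cohort),
    positive_outcome = tally(y == 1),
    admitted = tally(adm),
    stay_lt_24h = tally(adm & !is.na(stay) & stay < 24),
    stay_24_48h = tally(adm & !is.na(stay) & stay >= 24 & stay <= 48),
    stay_gt_48h = tally(adm & !is.na(stay) & stay > 48),
    readmitted_48h = tally(cohort$readmitted_within_48h == 1))
  if ("died" %in% names(cohort)) counts$mortality <- tally(cohort$died == 1)
  boundary <- lapply(list(low = low, high = high), function(t) {
    pt <- classification_metrics(risks, y, t)
    res <- list(threshold = t, metrics = pt,
                tp_fp_ratio = c(tp = unname(pt[["tp"]]), fp = unname(pt[["fp"]])))
    if (B > 0) {
      res$ci <- lapply(stats::setNames(nm = c("sensitivity", "specificity",
                                              "ppv", "npv", "lr_pos", "lr_neg")),
                       function(m) bootstrap_metric_ci(risks, y, m, threshold = t,
                                                       B = B, seed = seed))
    }
    res
  })
  structure(list(counts = counts, boundary = boundary,
                 low = low, high = high,
                 n = nrow(cohort), n_positive = sum(y == 1)),
            class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, digits = 3, ...) {
  cat(sprintf("Risk stratification (n = %d, %d positive outcomes)\n",
              x$n, x$n_positive))
  cat(sprintf("  boundaries: <=%.4f / >%.4f <=%.4f / >%.4f\n",
              x$low, x$low, x$high, x$high))
  df <- x$counts
  df$participants_pct <- sprintf("%.1f%%", 100 * df$participants_pct)
  print(df, row.names = FALSE)
  for (b in names(x$boundary)) {
    m <- x$boundary[[b]]$metrics
    cat(sprintf("  %s boundary %.4f: tp:fp %d:%d  sens %.2f spec %.2f ppv %.2f npv %.2f LR+ %.2f LR- %.2f\n",
                b, x$boundary[[b]]$threshold, m[["tp"]], m[["fp"]],
                m[["sensitivity"]], m[["specificity"]], m[["ppv"]],
                m[["npv"]], m[["lr_pos"]], m[["lr_neg"]]))
  }
  invisible(x)
}

#' Write a stratification report
#'
#' JSON document plus an optional plain-text table mirroring the printed
#' report layout.
#'
#' @param report a \code{stratification_report}.
#' @param json_path JSON output path.
#' @param text_path optional plain-text table path.
#' @return \code{json_path}, invisibly.
#' @export
write_stratification <- function(report, json_path, text_path = NULL) {
  doc <- list(class = "stratification_report",
              n = report$n, n_positive = report$n_positive,
              low = report$low, high = report$high,
              counts = report$counts,
              boundary = lapply(report$boundary, function(b) {
                list(threshold = b$threshold,
                     metrics = as.list(b$metrics),
                     tp_fp_ratio = as.list(b$tp_fp_ratio),
                     ci = b$ci)
              }))
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(json_path)
}

#' Stratify a cohort scored by a model
#'
#' Convenience wrapper: predicts risks, selects thresholds from the
#' targets (unless fixed thresholds are supplied), and builds the
#' report.
#'
#' @param cohort preprocessed cohort with a derived outcome.
#' @param model a \code{\link{triage_model}}.
#' @param thresholds optional fixed \code{c(low, high)}; when NULL,
#'   thresholds are selected from the targets on this cohort.
#' @param target_sensitivity,target_specificity threshold targets.
#' @param B bootstrap replicates for boundary-metric CIs.
#' @param seed integer seed.
#' @return a \code{stratification_report} with the \code{thresholds}
#'   attribute attached.
#' @export
stratify_cohort <- function(cohort, model, thresholds = NULL,
                            target_sensitivity = 0.90,
                            target_specificity = 0.90, B = 0L, seed = 1L) {
  risks <- predict(model, cohort, type = "response")
  if (is.null(thresholds)) {
    thresholds <- select_thresholds(risks, cohort$outcome,
                                    target_sensitivity, target_specificity)
  }
  rep <- build_report(cohort, risks, thresholds, B = B, seed = seed)
  attr(rep, "thresholds") <- thresholds
  rep
}
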