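#' Virtual-shunt transformation of oxygen saturation
#'
#' Re-expresses peripheral oxygen saturation (SpO2, percent) as the
#' equivalent intrapulmonary shunt fraction via the altitude-adaptive
#' virtual-shunt model \code{70.103 * log10(101.687 - spo2) - 55.833}.
#' The transform linearises the relationship between saturation and
#' impairment of gas exchange, which improves logistic-model fit: a drop
#' from 99 to 94 percent saturation reflects far less physiologic
#' derangement than a drop from 89 to 84.
#'
#' The function is strictly decreasing on \code{[0, 100]} and finite
#' everywhere on that interval because the offset constant exceeds 100.
#'
#' @param spo2 numeric vector of saturations in percent, in \code{[0, 100]}.
#'   \code{NA} values pass through as \code{NA}.
#' @param params optional list overriding the constants \code{a}, \code{b},
#'   \code{c} of \code{a * log10(b - spo2) - c}.
#' @return numeric vector of virtual-shunt values (percent shunt).
#' @examples
#' virtual_shunt(c(100, 98, 90))
#' @export
virtual_shunt <- function(spo2, params = virtual_shunt_params()) {
  bad <- !is.na(spo2) & (spo2 < 0 | spo2 > 100)
  if (any(bad)) {
    stopf("virtual_shunt: spo2 out of [0, 100]: %s",
          paste(utils::head(spo2[bad], 5L), collapse = ", "))
  }
  params$a * log10(params$b - spo2) - params$c
}

#' Constants of the virtual-shunt SpO2 transform
#'
#' @return list with elements \code{a}, \code{b}, \code{c}; \code{b > 100}
#'   keeps the transform finite over the whole saturation range.
#' @export
virtual_shunt_params <- function() {
  list(a = 70.103, b = 101.687, c = 55.833)
}

#' Composite admission outcome rule
#'
#' The model outcome is a surrogate for illness acuity: a child is a
#' positive case when admitted for at least \code{min_stay_hours} (default
#' 24 h, excluding brief observational admissions), or when initially sent
#' home but readmitted to a facility within \code{readmit_window_hours}
#' (default 48 h). \code{count_all_admissions = TRUE} is the robustness
#' variant in which any admission counts regardless of stay duration.
#' \code{strict_stay = TRUE} switches the stay comparison from \code{>=} to
#' \code{>}.
#'
#' @param min_stay_hours positive minimum stay, hours.
#' @param readmit_window_hours positive readmission window, hours
#'   (descriptive; the input flag is assumed already windowed).
#' @param count_all_admissions logical robustness switch.
#' @param strict_stay logical; use strict inequality on the stay.
#' @return an \code{outcome_rule} list.
#' @export
outcome_rule <- function(min_stay_hours = 24, readmit_window_hours = 48,
                         count_all_admissions = FALSE, strict_stay = FALSE) {
  if (min_stay_hours <= 0) stopf("outcome_rule: min_stay_hours must be > 0")
  if (readmit_window_hours <= 0) stopf("outcome_rule: readmit_window_hours must be > 0")
  structure(list(min_stay_hours = min_stay_hours,
                 readmit_window_hours = readmit_window_hours,
                 count_all_admissions = isTRUE(count_all_admissions),
                 strict_stay = isTRUE(strict_stay)),
            class = "outcome_rule")
}

#' Derive the composite admission outcome
#'
#' Applies an \code{\link{outcome_rule}} to the disposition fields of a
#' cohort: positive iff (admitted and stay meets the minimum) OR
#' (readmitted within the window) OR (admitted at all, under the
#' all-admissions robustness variant).
#'
#' @param cohort data frame with columns \code{admitted},
#'   \code{length_of_stay_hours}, \code{readmitted_within_48h}.
#' @param rule an \code{\link{outcome_rule}}.
#' @return the cohort with an integer \code{outcome} column appended.
#' @export
derive_outcome <- function(cohort, rule = outcome_rule()) {
  stopifnot(inherits(rule, "outcome_rule"))
  need <- c("admitted", "length_of_stay_hours", "readmitted_within_48h")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("derive_outcome: missing columns: %s", paste(miss, collapse = ", "))
  adm <- cohort$admitted
  if (!is_binary01(adm) || anyNA(adm)) stopf("derive_outcome: admitted must be 0/1 with no missing values")
  stay <- cohort$length_of_stay_hours
  bad <- which(adm == 1 & is.na(stay))
  if (length(bad)) {
    stopf("derive_outcome: admitted record(s) without length of stay at row(s): %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  stay_ok <- adm == 1 & !is.na(stay) &
    (if (rule$strict_stay) stay > rule$min_stay_hours else stay >= rule$min_stay_hours)
  readm <- !is.na(cohort$readmitted_within_48h) & cohort$readmitted_within_48h == 1
  out <- as.integer(stay_ok | readm | (rule$count_all_admissions & adm == 1))
  cohort$outcome <- out
  cohort
}

#' Median/mode imputation of predictor columns
#'
#' Continuous predictors receive the column median of the observed values;
#' binary/categorical predictors receive the column mode (ties broken
#' toward the smaller value, deterministically). Disposition and outcome
#' fields (\code{admitted}, \code{length_of_stay_hours},
#' \code{readmitted_within_48h}, \code{outcome}) are never imputed:
#' \code{length_of_stay_hours} is structurally absent for non-admitted
#' children, not missing.
#'
#' @param cohort data frame.
#' @param columns columns to impute; defaults to every column except
#'   identifiers and disposition/outcome fields.
#' @return cohort with no remaining \code{NA} in the imputed columns.
#' @export
impute_cohort <- function(cohort, columns = NULL) {
  skip <- c("patient_id", "admitted", "length_of_stay_hours",
            "readmitted_within_48h", "outcome")
  if (is.null(columns)) columns <- setdiff(names(cohort), skip)
  miss <- setdiff(columns, names(cohort))
  if (length(miss)) stopf("impute_cohort: unknown columns: %s", paste(miss, collapse = ", "))
  for (col in columns) {
    x <- cohort[[col]]
    if (!anyNA(x)) next
    obs <- x[!is.na(x)]
    if (!length(obs)) stopf("impute_cohort: column '%s' is entirely missing", col)
    fill <- if (is.numeric(obs) && !is_binary01(obs)) {
      stats::median(obs)
    } else {
      tab <- table(obs)
      best <- names(tab)[tab == max(tab)]
      v <- sort(best)[1L]  # tie -> smaller value
      if (is.numeric(obs)) as.numeric(v) else v
    }
    x[is.na(x)] <- fill
    cohort[[col]] <- x
  }
  cohort
}

#' Add the model's transformed predictor columns
#'
#' Appends \code{sqrt_age} (square root of age in months) and
#' \code{vs_spo2} (virtual-shunt transform of SpO2). Raw columns are left
#' intact. Imputation should already have been applied.
#'
#' @param cohort data frame with \code{age_months} and \code{spo2_pct}.
#' @return cohort with \code{sqrt_age} and \code{vs_spo2} appended.
#' @export
transform_predictors <- function(cohort) {
  if (!"age_months" %in% names(cohort)) stopf("transform_predictors: missing column 'age_months'")
  if (!"spo2_pct" %in% names(cohort)) stopf("transform_predictors: missing column 'spo2_pct'")
  if (any(cohort$age_months < 0, na.rm = TRUE)) stopf("transform_predictors: negative age_months")
  cohort$sqrt_age <- sqrt(cohort$age_months)
  cohort$vs_spo2 <- virtual_shunt(cohort$spo2_pct)
  cohort
}

#' Events-per-variable screen for binary candidate predictors
#'
#' Guards against overfitting the logistic model: a binary predictor is
#' excluded when fewer than \code{min_events} outcome-positive children
#' carry it (predictor = 1). Continuous predictors are exempt — an
#' events-per-variable count is undefined for them — and always retained.
#'
#' @param cohort data frame with a derived \code{outcome} column.
#' @param candidates character vector of candidate predictor columns.
#' @param min_events minimum events per binary variable (default 10).
#' @return list with \code{kept} (character vector) and \code{log}
#'   (data frame: predictor, type, event_count, kept).
#' @export
epv_screen <- function(cohort, candidates, min_events = 10) {
  if (min_events < 1) stopf("epv_screen: min_events must be >= 1")
  if (!"outcome" %in% names(cohort)) stopf("epv_screen: outcome not derived")
  miss <- setdiff(candidates, names(cohort))
  if (length(miss)) stopf("epv_screen: unknown candidates: %s", paste(miss, collapse = ", "))
  y <- cohort$outcome
  rows <- lapply(candidates, function(p) {
    x <- cohort[[p]]
    if (is_binary01(x)) {
      ev <- sum(y == 1 & x == 1, na.rm = TRUE)
      data.frame(predictor = p, type = "binary", event_count = ev,
                 kept = ev >= min_events, stringsAsFactors = FALSE)
    } else {
      data.frame(predictor = p, type = "continuous", event_count = NA_integer_,
                 kept = TRUE, stringsAsFactors = FALSE)
    }
  })
  log <- do.call(rbind, rows)
  kept <- log$predictor[log$kept]
  if (!length(kept)) warnf("epv_screen: no candidate predictors survive the screen")
  list(kept = kept, log = log)
}

#' Preprocess a raw cohort end to end
#'
#' Derives the composite outcome, imputes missing predictor values, and
#' appends the transformed predictors, in that order. Imputation
#' statistics are computed on the full cohort before any train/test split,
#' mirroring the development analysis's order of operations.
#'
#' @param cohort raw cohort data frame.
#' @param rule an \code{\link{outcome_rule}}.
#' @return preprocessed cohort.
#' @export
preprocess_cohort <- function(cohort, rule = outcome_rule()) {
  cohort <- derive_outcome(cohort, rule)
  cohort <- impute_cohort(cohort)
  transform_predictors(cohort)
}
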