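# The published nine-predictor triage score as a fixed scoring function.

#' Score a child with the published triage model
#'
#' Evaluates the published nine-predictor logistic equation on raw
#' inputs — age in months (square-rooted internally), heart rate,
#' axillary temperature, MUAC in millimetres, SpO2 (virtual-shunt
#' transformed internally) and the four binary signs — and assigns the
#' triage category at the deployed 0.08 / 0.40 risk thresholds. All
#' arguments are vectorised. Vitals are range-checked; no capping or
#' winsorisation is applied.
#'
#' Risk is strictly increasing in age, heart rate, temperature and each
#' sign, and strictly decreasing in MUAC and SpO2, matching the signs of
#' the published coefficients.
#'
#' @param age_months age at presentation, months (>= 0).
#' @param heart_rate_bpm heart rate, beats per minute (> 0).
#' @param temperature_c axillary temperature, degrees C in [33, 43].
#' @param muac_mm mid-upper arm circumference, millimetres (> 0).
#' @param spo2_pct peripheral oxygen saturation, percent in [50, 100].
#' @param parent_concern,difficulty_breathing,oedema,pallor 0/1 signs.
#' @return data frame with \code{risk} (probability, full precision),
#'   \code{risk_4dp} (rounded for display), \code{category},
#'   \code{sqrt_age}, \code{vs_spo2}.
#' @examples
#' triage_risk(12, 120, 37.0, 140, 98, 0, 0, 0, 0)  # ~0.025, non-urgent
#' @export
triage_risk <- function(age_months, heart_rate_bpm, temperature_c, muac_mm,
                        spo2_pct, parent_concern = 0,
                        difficulty_breathing = 0, oedema = 0, pallor = 0) {
  df <- data.frame(age_months, heart_rate_bpm, temperature_c, muac_mm,
                   spo2_pct, parent_concern, difficulty_breathing, oedema,
                   pallor)
  errs <- .check_score_row(df)
  if (any(nzchar(errs))) stopf("triage_risk: %s", errs[nzchar(errs)][1L])
  m <- published_triage_model()
  df <- transform_predictors(df)
  p <- predict(m, df, type = "response")
  data.frame(risk = p, risk_4dp = round(p, 4),
             category = categorize(p, m$thresholds[[1]], m$thresholds[[2]]),
             sqrt_age = df$sqrt_age, vs_spo2 = df$vs_spo2)
}

# per-row validation; returns "" for valid rows, else a message
.check_score_row <- function(df) {
  vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    probs <- character(0)
    need <- c("age_months", "heart_rate_bpm", "temperature_c", "muac_mm",
              "spo2_pct", "parent_concern", "difficulty_breathing",
              "oedema", "pallor")
    absent <- need[vapply(need, function(f) is.na(r[[f]]), logical(1))]
    if (length(absent)) {
      return(sprintf("absent field(s): %s", paste(absent, collapse = ", ")))
    }
    if (r$age_months < 0) probs <- c(probs, "age_months < 0")
    if (r$heart_rate_bpm <= 0) probs <- c(probs, "heart_rate_bpm <= 0")
    if (r$temperature_c < 33 || r$temperature_c > 43) probs <- c(probs, "temperature_c outside [33, 43]")
    if (r$muac_mm <= 0) probs <- c(probs, "muac_mm <= 0")
    if (r$spo2_pct < 50 || r$spo2_pct > 100) probs <- c(probs, "spo2_pct outside [50, 100]")
    for (f in c("parent_concern", "difficulty_breathing", "oedema", "pallor")) {
      if (!r[[f]] %in% c(0, 1)) probs <- c(probs, sprintf("%s not in {0, 1}", f))
    }
    if (length(probs)) sprintf("out-of-range field(s): %s", paste(probs, collapse = "; ")) else ""
  }, character(1))
}

#' Score a whole cohort with the published model
#'
#' Batch counterpart of \code{\link{triage_risk}}: appends risk,
#' category and the two transformed inputs to each valid row. Rows that
#' fail validation are collected into an error report and left unscored
#' (risk NA) instead of aborting the batch.
#'
#' @param cohort cohort data frame, or a path to a cohort CSV.
#' @param out_csv optional path; when given, the scored table is written
#'   there.
#' @return data frame of scored rows; attribute \code{errors} is a data
#'   frame (row, patient_id, message) of rows that could not be scored.
#' @export
score_cohort <- function(cohort, out_csv = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  m <- published_triage_model()
  out <- cohort
  out$risk <- rep(NA_real_, nrow(out))
  out$category <- rep(NA_character_, nrow(out))
  out$sqrt_age <- rep(NA_real_, nrow(out))
  out$vs_spo2 <- rep(NA_real_, nrow(out))
  errors <- data.frame(row = integer(0), patient_id = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  if (nrow(cohort) > 0) {
    msgs <- .check_score_row(cohort)
    bad <- nzchar(msgs)
    if (any(bad)) {
      errors <- data.frame(
        row = which(bad),
        patient_id = if ("patient_id" %in% names(cohort))
          cohort$patient_id[bad] else NA_character_,
        message = msgs[bad], stringsAsFactors = FALSE)
    }
    if (any(!bad)) {
      ok <- which(!bad)
      sc <- transform_predictors(cohort[ok, , drop = FALSE])
      p <- predict(m, sc, type = "response")
      out$risk[ok] <- p
      out$category[ok] <- as.character(
        categorize(p, m$thresholds[[1]], m$thresholds[[2]]))
      out$sqrt_age[ok] <- sc$sqrt_age
      out$vs_spo2[ok] <- sc$vs_spo2
    }
  }
  attr(out, "errors") <- errors
  if (!is.null(out_csv)) write_cohort(out, out_csv)
  out
}

#' Minimum sample size from the events-per-variable standard
#'
#' N = (n x EPV) / I for n expected predictors, outcome event rate I and
#' the standard of 10 events per effective variable; rounded up. Ten
#' predictors at a 20% event rate give the commonly quoted minimum of
#' 500 participants.
#'
#' @param n_predictors expected number of predictors in the final model.
#' @param event_rate anticipated outcome event rate in (0, 1].
#' @param events_per_variable events required per predictor (default 10).
#' @return integer minimum sample size.
#' @examples
#' sample_size(10, 0.20)  # 500
#' @export
sample_size <- function(n_predictors, event_rate, events_per_variable = 10) {
  if (n_predictors < 1 || events_per_variable < 1) {
    stopf("sample_size: counts must be >= 1")
  }
  if (event_rate <= 0 || event_rate > 1) {
    stopf("sample_size: event_rate must lie in (0, 1]")
  }
  as.integer(ceiling(n_predictors * events_per_variable / event_rate))
}
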