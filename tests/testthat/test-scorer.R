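# independent high-precision evaluation of the printed equation, kept
# free of the package's own transform helpers
oracle_risk <- function(age, hr, temp, muac, spo2, concern = 0, breath = 0,
                        oedema = 0, pallor = 0) {
  vs <- 70.103 * log10(101.687 - spo2) - 55.833
  lp <- -32.888 + 0.252 * sqrt(age) + 0.016 * hr + 0.819 * temp -
    0.022 * muac + 0.048 * vs + 1.793 * concern + 1.012 * breath +
    1.814 * oedema + 1.506 * pallor
  1 / (1 + exp(-lp))
}

test_that("the scorer reproduces the fixed equation to high precision", {
  low <- triage_risk(12, 120, 37.0, 140, 98)
  expect_equal(low$risk, oracle_risk(12, 120, 37.0, 140, 98), tolerance = 1e-12)
  expect_equal(low$risk_4dp, 0.0255)
  expect_equal(as.character(low$category), "non-urgent")
  high <- triage_risk(9, 180, 39.5, 120, 88, 1, 1, 0, 1)
  expect_equal(high$risk, oracle_risk(9, 180, 39.5, 120, 88, 1, 1, 0, 1),
               tolerance = 1e-12)
  expect_equal(high$risk_4dp, 0.9973)
  expect_equal(as.character(high$category), "emergency")
})

test_that("toggling a sign shifts the logit by exactly its coefficient", {
  base <- triage_risk(24, 130, 38, 135, 96, 0, 0, 0, 0)
  oed <- triage_risk(24, 130, 38, 135, 96, 0, 0, 1, 0)
  expect_equal(qlogis(oed$risk) - qlogis(base$risk), 1.814, tolerance = 1e-9)
})

test_that("risk is monotone in each predictor with the published signs", {
  args <- list(age_months = 24, heart_rate_bpm = 130, temperature_c = 38,
               muac_mm = 135, spo2_pct = 96, parent_concern = 0,
               difficulty_breathing = 0, oedema = 0, pallor = 0)
  base <- do.call(triage_risk, args)$risk
  up <- list(age_months = 1, heart_rate_bpm = 5, temperature_c = 0.5,
             muac_mm = 5, spo2_pct = 2, parent_concern = 1,
             difficulty_breathing = 1, oedema = 1, pallor = 1)
  signs <- c(age_months = 1, heart_rate_bpm = 1, temperature_c = 1,
             muac_mm = -1, spo2_pct = -1, parent_concern = 1,
             difficulty_breathing = 1, oedema = 1, pallor = 1)
  for (f in names(up)) {
    a <- args; a[[f]] <- a[[f]] + up[[f]]
    expect_equal(sign(do.call(triage_risk, a)$risk - base),
                 unname(signs[f]), label = f)
  }
})

test_that("out-of-range or absent inputs are rejected with the field named", {
  expect_error(triage_risk(12, 120, 37, 140, 101), "spo2_pct")
  expect_error(triage_risk(-1, 120, 37, 140, 98), "age_months")
  expect_error(triage_risk(12, 120, 37, 140, 98, parent_concern = 2),
               "parent_concern")
  expect_error(triage_risk(12, NA, 37, 140, 98), "heart_rate_bpm")
})

test_that("batch scoring equals single scoring and isolates bad rows", {
  coh <- make_cohort(80, seed = 50, raw = TRUE, missing = 0)
  scored <- score_cohort(coh)
  one <- triage_risk(coh$age_months[5], coh$heart_rate_bpm[5],
                     coh$temperature_c[5], coh$muac_mm[5], coh$spo2_pct[5],
                     coh$parent_concern[5], coh$difficulty_breathing[5],
                     coh$oedema[5], coh$pallor[5])
  expect_equal(scored$risk[5], one$risk)
  expect_equal(scored$category[5], as.character(one$category))
  expect_equal(nrow(attr(scored, "errors")), 0)
  # a row with invalid saturation is reported, the rest still scored
  coh$spo2_pct[3] <- 101
  scored2 <- score_cohort(coh)
  errs <- attr(scored2, "errors")
  expect_equal(errs$row, 3)
  expect_match(errs$message, "spo2_pct")
  expect_true(is.na(scored2$risk[3]))
  expect_false(anyNA(scored2$risk[-3]))
})

test_that("an empty cohort scores to an empty result without error", {
  coh <- make_cohort(5, seed = 1, raw = TRUE)[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  scored <- score_cohort(path)
  expect_equal(nrow(scored), 0)
  expect_equal(nrow(attr(scored, "errors")), 0)
})

test_that("the sample-size formula applies the events-per-variable standard", {
  expect_identical(sample_size(10, 0.20), 500L)
  expect_identical(sample_size(10, 1.0), 100L)
  expect_identical(sample_size(9, 0.18), 500L)
  expect_identical(sample_size(7, 0.33), 213L)  # ceiling of 212.1
  expect_error(sample_size(10, 0), "event_rate")
  expect_error(sample_size(0, 0.2), "counts")
})
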