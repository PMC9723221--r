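test_that("composite outcome rule covers stays, readmissions and variants", {
  d <- disposition_fixture()
  out <- derive_outcome(d)$outcome
  expect_identical(out, c(1L, 1L, 0L, 0L))  # 36 h stay; readmitted; 12 h stay; neither
  all_adm <- derive_outcome(d, outcome_rule(count_all_admissions = TRUE))$outcome
  expect_identical(all_adm, c(1L, 1L, 1L, 0L))
  # all-admissions positives are a superset of the default positives
  expect_true(all(all_adm >= out))
  # boundary: exactly 24 h counts by default, not under the strict flag
  d24 <- data.frame(admitted = 1L, length_of_stay_hours = 24,
                    readmitted_within_48h = 0L)
  expect_identical(derive_outcome(d24)$outcome, 1L)
  expect_identical(derive_outcome(d24, outcome_rule(strict_stay = TRUE))$outcome, 0L)
})

test_that("an admitted record without a stay is a data error", {
  d <- data.frame(admitted = c(1L, 1L), length_of_stay_hours = c(30, NA),
                  readmitted_within_48h = c(0L, 0L))
  expect_error(derive_outcome(d), "length of stay.*2")
  expect_error(outcome_rule(min_stay_hours = 0), "min_stay_hours")
})

test_that("median/mode imputation fills predictors deterministically", {
  d <- data.frame(x = c(1, 2, NA, 100), b = c(0, 0, 1, NA),
                  m = c(NA, 1, 1, 0))
  imp <- impute_cohort(d)
  expect_equal(imp$x[3], 2)   # median of the observed {1, 2, 100}
  expect_equal(imp$b[4], 0)   # mode
  expect_equal(imp$m[1], 1)   # mode 1 (two 1s vs one 0)
  # mode tie breaks toward the smaller value
  tie <- impute_cohort(data.frame(b = c(0, 1, NA)))
  expect_equal(tie$b[3], 0)
  # identity on complete data; idempotence
  full <- data.frame(x = c(1, 2, 3))
  expect_identical(impute_cohort(full), full)
  expect_identical(impute_cohort(imp), imp)
  expect_error(impute_cohort(data.frame(x = c(NA_real_, NA_real_))), "'x'")
})

test_that("imputation never touches disposition or outcome fields", {
  d <- data.frame(muac_mm = c(NA, 120), admitted = c(0L, 1L),
                  length_of_stay_hours = c(NA, 30),
                  readmitted_within_48h = c(0L, 0L))
  imp <- impute_cohort(d)
  expect_true(is.na(imp$length_of_stay_hours[1]))
  expect_false(anyNA(imp$muac_mm))
})

test_that("virtual shunt matches the closed-form transform", {
  # oracle: direct high-precision evaluation of a*log10(b - s) - c
  expect_equal(virtual_shunt(90), 19.02, tolerance = 0.01 / 19.02)
  expect_equal(virtual_shunt(100), -39.91, tolerance = 0.01 / 39.91)
  expect_equal(virtual_shunt(98), 70.103 * log10(101.687 - 98) - 55.833,
               tolerance = 1e-12)
  expect_gt(virtual_shunt(95), virtual_shunt(99))
  # strictly decreasing over the whole saturation range
  grid <- virtual_shunt(seq(0, 100, by = 0.5))
  expect_true(all(diff(grid) < 0))
  expect_error(virtual_shunt(101), "out of")
  expect_error(virtual_shunt(-1), "out of")
})

test_that("predictor transforms add sqrt age and shunt columns", {
  d <- data.frame(age_months = c(144, 0), spo2_pct = c(98, 90))
  tr <- transform_predictors(d)
  expect_equal(tr$sqrt_age, c(12, 0))
  expect_equal(tr$vs_spo2[1], -16.11, tolerance = 0.01 / 16.11)
  expect_true(all(c("age_months", "spo2_pct") %in% names(tr)))
  expect_error(transform_predictors(data.frame(age_months = -1, spo2_pct = 95)),
               "negative age")
})

test_that("events-per-variable screen drops sparse binary predictors only", {
  n <- 60
  d <- data.frame(outcome = rep(c(1L, 0L), c(20, 40)),
                  rare9 = c(rep(1L, 9), rep(0L, n - 9)),
                  ok10 = c(rep(1L, 10), rep(0L, n - 10)),
                  cont = rnorm(n))
  sc <- epv_screen(d, c("rare9", "ok10", "cont"))
  expect_setequal(sc$kept, c("ok10", "cont"))
  expect_equal(sc$log$event_count[sc$log$predictor == "rare9"], 9)
  expect_true(is.na(sc$log$event_count[sc$log$predictor == "cont"]))
  # zero positive outcomes: every binary candidate is dropped, with warning
  d0 <- transform(d, outcome = 0L)
  expect_warning(sc0 <- epv_screen(d0, c("rare9", "ok10")), "no candidate")
  expect_length(sc0$kept, 0)
})

test_that("epv keep-list shrinks monotonically as the threshold rises", {
  coh <- make_cohort(800, seed = 9, noise = 3)
  cand <- candidate_predictors(coh)
  prev <- NULL
  for (m in c(1, 5, 10, 20, 40)) {
    kept <- suppressWarnings(epv_screen(coh, cand, min_events = m)$kept)
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})
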