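test_that("rank AUROC agrees with brute-force pairwise comparison", {
  # worked example: 3 of the 4 positive-negative pairs are concordant
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)  # all ties
  y <- rep(c(0, 1), 8)
  expect_equal(auroc(y, y), 1)
  expect_error(auroc(c(0.2, 0.4), c(1, 1)), "both")
  # brute-force oracle on random vectors with ties
  set.seed(20)
  for (i in 1:5) {
    r <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
    brute <- mean(ifelse(r[pairs$p] > r[pairs$n], 1,
                         ifelse(r[pairs$p] == r[pairs$n], 0.5, 0)))
    expect_equal(auroc(r, y), brute)
  }
})

test_that("ROC curve is monotone and its trapezoid area equals the rank AUROC", {
  set.seed(21)
  r <- runif(200); y <- rbinom(200, 1, plogis(3 * r - 1.5))
  rc <- roc_curve(r, y)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(trap, auroc(r, y), tolerance = 1e-12)
})

test_that("rank AUROC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  r <- runif(300); y <- rbinom(300, 1, plogis(4 * r - 2))
  expect_equal(auroc(r, y),
               as.numeric(pROC::auc(pROC::roc(y, r, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("every row gets exactly one out-of-fold prediction", {
  coh <- make_cohort(600, seed = 23)
  risks <- cross_validated_predictions(coh, c("sqrt_age", "temperature_c"),
                                       n_folds = 10, seed = 1)
  expect_false(anyNA(risks))
  expect_length(risks, nrow(coh))
  fold <- attr(risks, "fold")
  expect_setequal(unique(fold), 1:10)
  # stratification keeps both classes in every training fold
  for (k in 1:10) expect_gt(length(unique(coh$outcome[fold != k])), 1)
})

test_that("cross-validated AUROC hits the known extremes", {
  # perfectly separable data
  d <- data.frame(x = c(rnorm(100, -4), rnorm(100, 4)),
                  outcome = rep(0:1, each = 100))
  r <- cross_validated_predictions(d, "x", n_folds = 5, seed = 2)
  expect_equal(auroc(r, d$outcome), 1)
  # outcome independent of the predictors: null discrimination
  set.seed(24)
  null <- data.frame(x1 = rnorm(10000), x2 = rnorm(10000),
                     outcome = rbinom(10000, 1, 0.25))
  rn <- cross_validated_predictions(null, c("x1", "x2"), n_folds = 10, seed = 3)
  expect_lt(abs(auroc(rn, null$outcome) - 0.5), 0.02)
})

test_that("cross-validated AUROC recovers the generating model's discrimination", {
  set.seed(25)
  n <- 4000
  d <- data.frame(x = rnorm(n))
  p <- plogis(-1.5 + 1.3 * d$x)
  d$outcome <- rbinom(n, 1, p)
  # oracle: Monte-Carlo AUROC of the true risk at large n
  xo <- rnorm(2e5); po <- plogis(-1.5 + 1.3 * xo)
  target <- auroc(po, rbinom(2e5, 1, po))
  r <- cross_validated_predictions(d, "x", n_folds = 10, seed = 4)
  expect_lt(abs(auroc(r, d$outcome) - target), 0.02)
})

test_that("out-of-fold AUROC does not exceed the apparent AUROC materially", {
  aucs <- vapply(1:3, function(s) {
    coh <- make_cohort(5000, seed = 30 + s)
    preds <- c("sqrt_age", "temperature_c", "parent_concern", "vs_spo2")
    oof <- cross_validated_predictions(coh, preds, n_folds = 10, seed = s)
    m <- fit_triage_model(coh, preds)
    c(oof = auroc(oof, coh$outcome),
      apparent = auroc(predict(m, coh), coh$outcome))
  }, numeric(2))
  expect_lte(mean(aucs["oof", ] - aucs["apparent", ]), 0.02)
})

test_that("bootstrap metric intervals behave at the boundaries", {
  risks <- c(rep(0.1, 50), rep(0.9, 50))
  y <- rep(c(0, 1), each = 50)
  ci <- bootstrap_metric_ci(risks, y, "sensitivity", threshold = 0.5, B = 200)
  expect_equal(ci$point, 1)
  expect_equal(c(ci$low, ci$high), c(1, 1))
  # point estimate equals the plug-in metric on the original sample
  set.seed(26)
  r <- runif(150); yy <- rbinom(150, 1, r)
  ci2 <- bootstrap_metric_ci(r, yy, "specificity", threshold = 0.4, B = 200)
  expect_equal(ci2$point,
               unname(classification_metrics(r, yy, 0.4)[["specificity"]]))
  expect_true(ci2$low <= ci2$point && ci2$point <= ci2$high)
})

test_that("bootstrap SE stabilises as replicates grow", {
  set.seed(27)
  r <- runif(120); y <- rbinom(120, 1, r)
  se1 <- bootstrap_metric_ci(r, y, "auroc", B = 2000, seed = 1)$se
  se2 <- bootstrap_metric_ci(r, y, "auroc", B = 4000, seed = 2)$se
  expect_lt(abs(se1 - se2) / se1, 0.15)
})

test_that("likelihood ratios satisfy their defining identities", {
  set.seed(28)
  r <- runif(400); y <- rbinom(400, 1, r)
  m <- classification_metrics(r, y, 0.5)
  expect_equal(m[["lr_pos"]], m[["sensitivity"]] / (1 - m[["specificity"]]))
  expect_equal(m[["lr_neg"]], (1 - m[["sensitivity"]]) / m[["specificity"]])
})

test_that("calibration detects the truth, a constant, and anti-calibration", {
  set.seed(29)
  n <- 5000
  p <- plogis(rnorm(n, -1.5, 1.2))
  y <- rbinom(n, 1, p)
  cc <- calibration_curve(p, y, B = 100, seed = 1)
  expect_lt(abs(cc$slope - 1), 0.15)
  expect_true(all(is.finite(cc$curve$corrected)))
  # constant risk equal to prevalence: a single effective bin
  const <- calibration_curve(rep(mean(y), n), y, B = 0)
  expect_equal(const$n_bins, 1)
  expect_equal(const$curve$observed[1], mean(y))
  # reversed risks: negative calibration slope
  anti <- calibration_curve(1 - p, y, B = 0)
  expect_lt(anti$slope, 0)
})

test_that("the evaluation report assembles all components coherently", {
  coh <- make_cohort(1200, seed = 33)
  ev <- evaluate_model(coh, c("sqrt_age", "temperature_c", "parent_concern",
                              "vs_spo2"),
                       thresholds = c(0.08, 0.40),
                       n_bootstrap_metrics = 200,
                       n_bootstrap_calibration = 100,
                       n_split_repeats = 3, seed = 5)
  expect_s3_class(ev, "triage_evaluation")
  expect_true(ev$pooled_auroc$point > 0.5 && ev$pooled_auroc$point <= 1)
  expect_true(ev$pooled_auroc$low <= ev$pooled_auroc$point)
  expect_length(ev$per_fold_auroc, 10)
  # sensitivity is non-increasing in the threshold
  sens <- vapply(ev$threshold_metrics,
                 function(tm) tm$point[["sensitivity"]], numeric(1))
  expect_true(all(diff(sens) <= 0))
  expect_length(ev$split$per_repeat, 3)
  # artifacts write and parse back
  jp <- withr::local_tempfile(fileext = ".json")
  rp <- withr::local_tempfile(fileext = ".csv")
  write_evaluation(ev, coh$outcome, jp, roc_path = rp)
  doc <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(doc$pooled_auroc$point, ev$pooled_auroc$point)
  expect_true(file.exists(rp))
})

test_that("the robustness variants run end to end and report an AUROC", {
  raw <- make_cohort(1500, seed = 34, raw = TRUE)
  u5 <- preprocess_cohort(raw[raw$age_months < 60, ])
  preds <- c("sqrt_age", "temperature_c", "parent_concern", "vs_spo2")
  ev_u5 <- evaluate_model(u5, preds, n_bootstrap_metrics = 150,
                          n_bootstrap_calibration = 0, seed = 6)
  expect_true(is.finite(ev_u5$pooled_auroc$point))
  all_adm <- preprocess_cohort(raw, outcome_rule(count_all_admissions = TRUE))
  ev_all <- evaluate_model(all_adm, preds, n_bootstrap_metrics = 150,
                           n_bootstrap_calibration = 0, seed = 7)
  expect_true(is.finite(ev_all$pooled_auroc$point))
  expect_gte(sum(all_adm$outcome), sum(preprocess_cohort(raw)$outcome))
})
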