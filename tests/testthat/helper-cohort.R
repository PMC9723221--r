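# Shared fixtures: small cohorts built in code.

# seeded synthetic cohort, preprocessed unless raw = TRUE
make_cohort <- function(n, seed = 1L, noise = 0L, missing = 0,
                        raw = FALSE, ...) {
  cfg <- cohort_config(n_patients = n, seed = seed,
                       noise_predictor_count = noise,
                       missingness_rate = missing, ...)
  coh <- generate_cohort(cfg)
  if (raw) coh else preprocess_cohort(coh)
}

# hand-built four-row disposition table for outcome-rule tests
disposition_fixture <- function() {
  data.frame(
    patient_id = paste0("P", 1:4),
    admitted = c(1L, 0L, 1L, 0L),
    length_of_stay_hours = c(36, NA, 12, NA),
    readmitted_within_48h = c(0L, 1L, 0L, 0L))
}

true_predictors <- function() {
  names(published_triage_model()$coefficients)
}

# exhaustive best-subset AIC oracle over a small candidate set
best_subset_aic <- function(cohort, candidates, outcome = "outcome") {
  stopifnot(length(candidates) <= 5)
  best <- NULL; best_aic <- Inf
  for (k in 0:length(candidates)) {
    for (set in utils::combn(candidates, k, simplify = FALSE)) {
      fml <- if (length(set)) reformulate(set, outcome) else
        reformulate("1", outcome)
      aic <- AIC(glm(fml, data = cohort, family = binomial()))
      if (aic < best_aic - 1e-8) { best <- sort(unlist(set)); best_aic <- aic }
    }
  }
  list(set = as.character(best), aic = best_aic)
}
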