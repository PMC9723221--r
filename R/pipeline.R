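# End-to-end orchestration: generate -> preprocess -> select -> fit ->
# evaluate -> stratify, as one seeded, manifest-tracked run.

#' Build a pipeline run configuration
#'
#' One master seed deterministically derives every stage seed, so an
#' identical configuration yields byte-identical artifacts. Defaults
#' mirror the development analysis: 2,000 bootstrap replicates with an
#' 80% consensus threshold, 10 cross-validation folds, and 90%/90%
#' sensitivity/specificity threshold targets.
#'
#' @param cohort_csv path to an input cohort CSV; NULL generates a
#'   synthetic cohort from \code{generator}.
#' @param generator a \code{\link{cohort_config}} used when no input
#'   cohort is given (its seed is overridden by the derived stage seed).
#' @param outcome an \code{\link{outcome_rule}}; set
#'   \code{count_all_admissions = TRUE} for the all-admissions
#'   robustness variant.
#' @param under5_only restrict the analysis to children under 60 months.
#' @param min_events events-per-variable screen threshold.
#' @param n_bootstrap,inclusion_threshold consensus selection settings.
#' @param n_folds,n_bootstrap_metrics,n_bootstrap_calibration evaluation
#'   settings.
#' @param target_sensitivity,target_specificity stratification targets.
#' @param strat_bootstrap bootstrap replicates for boundary-metric CIs.
#' @param seed master seed.
#' @return a \code{triage_run_config} list.
#' @export
triage_run_config <- function(cohort_csv = NULL,
                              generator = cohort_config(),
                              outcome = outcome_rule(),
                              under5_only = FALSE,
                              min_events = 10,
                              n_bootstrap = 2000L,
                              inclusion_threshold = 0.80,
                              n_folds = 10L,
                              n_bootstrap_metrics = 2000L,
                              n_bootstrap_calibration = 1000L,
                              target_sensitivity = 0.90,
                              target_specificity = 0.90,
                              strat_bootstrap = 0L,
                              seed = 1L) {
  structure(list(cohort_csv = cohort_csv, generator = generator,
                 outcome = outcome, under5_only = isTRUE(under5_only),
                 min_events = min_events, n_bootstrap = as.integer(n_bootstrap),
                 inclusion_threshold = inclusion_threshold,
                 n_folds = as.integer(n_folds),
                 n_bootstrap_metrics = as.integer(n_bootstrap_metrics),
                 n_bootstrap_calibration = as.integer(n_bootstrap_calibration),
                 target_sensitivity = target_sensitivity,
                 target_specificity = target_specificity,
                 strat_bootstrap = as.integer(strat_bootstrap),
                 seed = as.integer(seed)),
            class = "triage_run_config")
}

# stable JSON rendering of a config (drops the embedded model object's
# environment-free parts only; used for the manifest hash)
.config_json <- function(config) {
  ser <- config
  ser$generator$true_model <- list(
    intercept = config$generator$true_model$intercept,
    coefficients = as.list(config$generator$true_model$coefficients))
  ser$outcome <- unclass(ser$outcome)
  ser$generator <- unclass(ser$generator)
  jsonlite::toJSON(unclass(ser), auto_unbox = TRUE, digits = NA,
                   null = "null", na = "null")
}

#' Write / read a pipeline configuration file
#'
#' The configuration serialises to a human-editable JSON document and
#' reads back unchanged (the generator's true model is stored as its
#' intercept and coefficients).
#'
#' @param config a \code{\link{triage_run_config}}.
#' @param path file path.
#' @return \code{write_run_config} the path invisibly;
#'   \code{read_run_config} a \code{triage_run_config}.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "triage_run_config"))
  writeLines(as.character(.config_json(config)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tm <- triage_model(intercept = doc$generator$true_model$intercept,
                     coefficients = unlist(doc$generator$true_model$coefficients),
                     source = "config")
  gen <- cohort_config(
    n_patients = doc$generator$n_patients,
    seed = doc$generator$seed,
    true_model = tm,
    target_event_rate = doc$generator$target_event_rate,
    intercept_offset = doc$generator$intercept_offset,
    noise_predictor_count = doc$generator$noise_predictor_count,
    missingness_rate = doc$generator$missingness_rate,
    age_mixture = as.data.frame(doc$generator$age_mixture),
    symptom_prevalence = as.list(doc$generator$symptom_prevalence),
    short_stay_frac = doc$generator$short_stay_frac,
    returned_frac = doc$generator$returned_frac,
    female_frac = doc$generator$female_frac)
  rule <- outcome_rule(doc$outcome$min_stay_hours,
                       doc$outcome$readmit_window_hours,
                       doc$outcome$count_all_admissions,
                       doc$outcome$strict_stay)
  triage_run_config(cohort_csv = doc$cohort_csv, generator = gen,
                    outcome = rule, under5_only = doc$under5_only,
                    min_events = doc$min_events,
                    n_bootstrap = doc$n_bootstrap,
                    inclusion_threshold = doc$inclusion_threshold,
                    n_folds = doc$n_folds,
                    n_bootstrap_metrics = doc$n_bootstrap_metrics,
                    n_bootstrap_calibration = doc$n_bootstrap_calibration,
                    target_sensitivity = doc$target_sensitivity,
                    target_specificity = doc$target_specificity,
                    strat_bootstrap = doc$strat_bootstrap,
                    seed = doc$seed)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(.config_json(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full model-development pipeline
#'
#' Executes every stage on one cohort and writes all artifacts to
#' \code{out_dir}: the (possibly generated) cohort CSV, the
#' events-per-variable exclusion log, the inclusion-frequency report,
#' the final model JSON, the evaluation JSON with ROC/calibration CSV
#' curves, the stratification JSON and text table, a run log, and a
#' manifest naming the configuration hash and seed that produced them.
#'
#' @param config a \code{\link{triage_run_config}}.
#' @param out_dir artifacts directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (\code{cohort}, \code{screen}, \code{selection}, \code{model},
#'   \code{evaluation}, \code{stratification}, \code{thresholds},
#'   \code{manifest}).
#' @export
run_triage_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "triage_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
    writeLines(log_lines, log_path)
  }
  seeds <- derive_seeds(config$seed, 4L)
  stage <- "generate"
  res <- tryCatch({
    if (is.null(config$cohort_csv)) {
      gen <- config$generator
      gen$seed <- seeds[1L]
      cohort <- generate_cohort(gen)
      say("generate: synthetic cohort n = %d (seed %d)", nrow(cohort), gen$seed)
    } else {
      cohort <- read_cohort(config$cohort_csv)
      say("load: cohort n = %d from %s", nrow(cohort), config$cohort_csv)
    }
    write_cohort(cohort, file.path(out_dir, "cohort.csv"), schema = TRUE)

    stage <- "preprocess"
    if (config$under5_only) {
      cohort <- cohort[cohort$age_months < 60, , drop = FALSE]
      say("subgroup: restricted to under-5s, n = %d", nrow(cohort))
    }
    cohort <- preprocess_cohort(cohort, config$outcome)
    say("preprocess: %d positive outcomes (%.1f%%)%s", sum(cohort$outcome),
        100 * mean(cohort$outcome),
        if (config$outcome$count_all_admissions) " [all-admissions variant]" else "")
    cand <- candidate_predictors(cohort)
    screen <- epv_screen(cohort, cand, config$min_events)
    for (i in which(!screen$log$kept)) {
      say("epv_screen: dropped %s (%d events)", screen$log$predictor[i],
          screen$log$event_count[i])
    }
    utils::write.csv(screen$log, file.path(out_dir, "epv_exclusions.csv"),
                     row.names = FALSE)

    stage <- "select"
    dev <- develop_triage_model(cohort, screen$kept,
                                n_bootstrap = config$n_bootstrap,
                                inclusion_threshold = config$inclusion_threshold,
                                seed = seeds[2L])
    if (dev$selection$n_skipped_replicates > 0) {
      say("selection: %d replicate(s) skipped (single outcome class)",
          dev$selection$n_skipped_replicates)
    }
    say("selection: consensus set (%d): %s", length(dev$selection$consensus_set),
        paste(dev$selection$consensus_set, collapse = ", "))
    if (dev$model$separation) say("fit: separation detected; ridge fallback used")
    write_selection_csv(dev$selection, file.path(out_dir, "inclusion_frequency.csv"))
    write_model_json(dev$model, file.path(out_dir, "model.json"))

    stage <- "evaluate"
    ev <- evaluate_model(cohort, dev$selection$consensus_set,
                         n_folds = config$n_folds,
                         n_bootstrap_metrics = config$n_bootstrap_metrics,
                         n_bootstrap_calibration = config$n_bootstrap_calibration,
                         seed = seeds[3L])
    say("evaluate: pooled AUROC %.3f (%.3f, %.3f); calibration slope %.3f",
        ev$pooled_auroc$point, ev$pooled_auroc$low, ev$pooled_auroc$high,
        ev$calibration$slope)
    write_evaluation(ev, cohort$outcome,
                     json_path = file.path(out_dir, "evaluation.json"),
                     roc_path = file.path(out_dir, "roc_curve.csv"),
                     calibration_path = file.path(out_dir, "calibration_curve.csv"))

    stage <- "stratify"
    strat <- stratify_cohort(cohort, dev$model,
                             target_sensitivity = config$target_sensitivity,
                             target_specificity = config$target_specificity,
                             B = config$strat_bootstrap, seed = seeds[4L])
    th <- attr(strat, "thresholds")
    say("stratify: thresholds low %.4f / high %.4f", th$low, th$high)
    write_stratification(strat, file.path(out_dir, "stratification.json"),
                         file.path(out_dir, "stratification.txt"))

    manifest <- list(config_hash = .config_hash(config),
                     seed = config$seed,
                     stage_seeds = as.integer(seeds),
                     package_version = as.character(utils::packageVersion("pedtriage")),
                     r_version = as.character(getRversion()),
                     artifacts = c("cohort.csv", "epv_exclusions.csv",
                                   "inclusion_frequency.csv", "model.json",
                                   "evaluation.json", "roc_curve.csv",
                                   "calibration_curve.csv",
                                   "stratification.json", "stratification.txt",
                                   "run_log.txt"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    say("done: manifest %s", manifest$config_hash)
    list(cohort = cohort, screen = screen, selection = dev$selection,
         model = dev$model, evaluation = ev, stratification = strat,
         thresholds = th, manifest = manifest)
  }, error = function(e) {
    say("ERROR in stage '%s': %s", stage, conditionMessage(e))
    stopf("run_triage_pipeline failed in stage '%s': %s", stage,
          conditionMessage(e))
  })
  invisible(res)
}
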