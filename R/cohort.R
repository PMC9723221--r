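#' Configuration for the synthetic cohort generator
#'
#' Describes a synthetic pediatric emergency-department cohort with the
#' statistical structure the triage analysis assumes: an age mixture
#' dominated by under-fives, age-conditional vital signs and
#' anthropometry, binary danger signs, optional pure-noise decoy
#' predictors, completely-at-random missingness, and a composite
#' admission outcome generated from a known logistic model so that every
#' downstream stage is testable with known truth.
#'
#' The latent outcome probability is the \code{true_model} (default: the
#' published nine-predictor model) evaluated on the generated predictors
#' with exactly the transforms the preprocessing stage applies. The
#' intercept offset is solved by root-finding on the mean probability when
#' a target event rate is requested; passing \code{intercept_offset}
#' directly bypasses the calibration.
#'
#' @param n_patients number of children (>= 1).
#' @param seed integer seed; identical config + seed gives an identical
#'   cohort.
#' @param true_model \code{\link{triage_model}} generating the outcome.
#' @param target_event_rate desired marginal rate of the composite
#'   outcome; ignored when \code{intercept_offset} is supplied.
#' @param intercept_offset additive logit offset (e.g. -50 silences the
#'   outcome entirely).
#' @param noise_predictor_count number of binary decoy predictors
#'   \code{noise_1..K} (prevalence 0.3), unrelated to the outcome.
#' @param missingness_rate per-column MCAR fraction in [0, 0.05), applied
#'   to vitals, anthropometry and signs after generation.
#' @param age_mixture data frame with columns \code{lo}, \code{hi}
#'   (months) and \code{weight}; ages are uniform within the sampled band.
#' @param symptom_prevalence named list of prevalences for
#'   \code{parent_concern}, \code{difficulty_breathing}, \code{oedema},
#'   \code{pallor}.
#' @param short_stay_frac fraction of admitted children whose stay is
#'   under 24 h (admissions that do not count as positive outcomes).
#' @param returned_frac fraction of positive outcomes that arise through
#'   the sent-home-then-readmitted-within-48 h route rather than a >= 24 h
#'   admission; the default 0.052 yields about 1.5% readmissions among
#'   the non-admitted.
#' @param female_frac probability of female sex.
#' @return a \code{cohort_config} list.
#' @export
cohort_config <- function(n_patients = 1612,
                          seed = 1L,
                          true_model = published_triage_model(),
                          target_event_rate = 0.226,
                          intercept_offset = NULL,
                          noise_predictor_count = 0L,
                          missingness_rate = 0.02,
                          age_mixture = default_age_mixture(),
                          symptom_prevalence = list(parent_concern = 0.25,
                                                    difficulty_breathing = 0.20,
                                                    oedema = 0.02,
                                                    pallor = 0.08),
                          short_stay_frac = 0.10,
                          returned_frac = 0.052,
                          female_frac = 0.485) {
  if (n_patients < 1) stopf("cohort_config: n_patients must be >= 1")
  if (!is.null(target_event_rate) &&
      (target_event_rate <= 0 || target_event_rate >= 1)) {
    stopf("cohort_config: target_event_rate must lie in (0, 1)")
  }
  if (missingness_rate < 0 || missingness_rate >= 0.05) {
    stopf("cohort_config: missingness_rate must lie in [0, 0.05)")
  }
  if (any(age_mixture$weight < 0) || sum(age_mixture$weight) <= 0) {
    stopf("cohort_config: age_mixture weights must be >= 0 with positive sum")
  }
  if (short_stay_frac < 0 || short_stay_frac >= 1) {
    stopf("cohort_config: short_stay_frac must lie in [0, 1)")
  }
  if (returned_frac < 0 || returned_frac >= 1) {
    stopf("cohort_config: returned_frac must lie in [0, 1)")
  }
  stopifnot(inherits(true_model, "triage_model"))
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 true_model = true_model,
                 target_event_rate = target_event_rate,
                 intercept_offset = intercept_offset,
                 noise_predictor_count = as.integer(noise_predictor_count),
                 missingness_rate = missingness_rate,
                 age_mixture = age_mixture,
                 symptom_prevalence = symptom_prevalence,
                 short_stay_frac = short_stay_frac,
                 returned_frac = returned_frac,
                 female_frac = female_frac),
            class = "cohort_config")
}

#' Default age mixture of the synthetic cohort
#'
#' Age bands (months) and weights approximating a young low-resource
#' pediatric ED population: about 89% under five years.
#'
#' @return data frame with \code{lo}, \code{hi} (months), \code{weight}.
#' @export
default_age_mixture <- function() {
  data.frame(lo = c(0, 1, 12, 24, 60, 120),
             hi = c(1, 12, 24, 60, 120, 180),
             weight = c(0.050, 0.393, 0.252, 0.197, 0.089, 0.019))
}

# age-conditional reference means for vitals/anthropometry (pediatric
# normal ranges, shifted toward an acutely ill population)
.vital_band <- function(age_months) {
  findInterval(age_months, c(0, 12, 24, 60, 120), rightmost.closed = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws predictors from the configured marginals, computes each child's
#' latent outcome probability from the true model (square-root age and
#' virtual-shunt SpO2 transforms applied exactly as in preprocessing),
#' draws the composite admission outcome, and decomposes it into
#' consistent disposition fields: most positives are admissions with stay
#' >= 24 h, a small fraction are sent home and readmitted within 48 h,
#' and a configurable share of admissions are short (< 24 h) stays that do
#' not count as positive outcomes. \code{\link{derive_outcome}} applied to
#' the generated disposition fields reproduces the generating outcome
#' exactly.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return data frame of one row per child; attributes \code{config},
#'   \code{intercept_offset} (the solved calibration offset) and
#'   \code{latent_rate} (mean latent probability) are attached.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 200, seed = 42))
#' mean(derive_outcome(coh)$outcome)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  with_local_seed(config$seed, {
    mix <- config$age_mixture
    band <- sample.int(nrow(mix), n, replace = TRUE,
                       prob = mix$weight / sum(mix$weight))
    age <- stats::runif(n, mix$lo[band], mix$hi[band])
    sex <- ifelse(stats::rbinom(n, 1L, config$female_frac) == 1, "female", "male")
    vb <- .vital_band(age)
    hr <- pmax(40, stats::rnorm(n, c(140, 125, 115, 100, 90)[vb], 18))
    rr <- pmax(8, stats::rnorm(n, c(45, 35, 30, 24, 20)[vb], 8))
    temp <- pmin(43, pmax(33, stats::rnorm(n, 37.8, 1.1)))
    mb <- findInterval(age, c(0, 6, 24, 60, 120))
    muac <- pmax(80, stats::rnorm(n, c(120, 140, 150, 170, 210)[mb], 14))
    spo2 <- pmax(50, pmin(100, 100 - stats::rgamma(n, shape = 1.5, scale = 1.8)))
    sp <- config$symptom_prevalence
    cohort <- data.frame(
      patient_id = sprintf("PT%06d", seq_len(n)),
      age_months = age,
      sex = sex,
      heart_rate_bpm = hr,
      temperature_c = temp,
      muac_mm = muac,
      spo2_pct = spo2,
      respiratory_rate_bpm = rr,
      parent_concern = stats::rbinom(n, 1L, sp$parent_concern),
      difficulty_breathing = stats::rbinom(n, 1L, sp$difficulty_breathing),
      oedema = stats::rbinom(n, 1L, sp$oedema),
      pallor = stats::rbinom(n, 1L, sp$pallor),
      stringsAsFactors = FALSE)
    if (config$noise_predictor_count > 0) {
      for (k in seq_len(config$noise_predictor_count)) {
        cohort[[paste0("noise_", k)]] <- stats::rbinom(n, 1L, 0.3)
      }
    }

    # latent outcome probability from the true model
    lp <- predict(config$true_model, cohort, type = "link")
    offset <- config$intercept_offset
    if (is.null(offset)) {
      offset <- if (is.null(config$target_event_rate)) 0 else
        .solve_offset(lp, config$target_event_rate)
    }
    p <- stats::plogis(lp + offset)
    y <- stats::rbinom(n, 1L, p)

    # decompose the composite outcome into disposition fields
    admitted <- integer(n)
    stay <- rep(NA_real_, n)
    readmit <- integer(n)
    pos <- which(y == 1)
    returned <- pos[stats::rbinom(length(pos), 1L, config$returned_frac) == 1]
    long <- setdiff(pos, returned)
    readmit[returned] <- 1L
    admitted[long] <- 1L
    stay[long] <- 24 + stats::rexp(length(long), rate = 1 / 62)
    neg <- which(y == 0)
    n_short <- round(config$short_stay_frac / (1 - config$short_stay_frac) *
                       length(long))
    n_short <- min(n_short, length(neg))
    if (n_short > 0) {
      short <- if (length(neg) == 1L) neg else sample(neg, n_short)
      admitted[short] <- 1L
      stay[short] <- stats::runif(n_short, 2, 24 - 1e-6)
    }
    cohort$admitted <- admitted
    cohort$length_of_stay_hours <- stay
    cohort$readmitted_within_48h <- readmit

    # MCAR missingness on measured predictors only
    if (config$missingness_rate > 0) {
      measured <- c("heart_rate_bpm", "temperature_c", "muac_mm", "spo2_pct",
                    "respiratory_rate_bpm", "parent_concern",
                    "difficulty_breathing", "oedema", "pallor")
      for (col in measured) {
        drop <- stats::runif(n) < config$missingness_rate
        cohort[[col]][drop] <- NA
      }
    }
    attr(cohort, "config") <- config
    attr(cohort, "intercept_offset") <- offset
    attr(cohort, "latent_rate") <- mean(p)
    cohort
  })
}

# calibrate the logit offset so the mean latent probability hits `target`
.solve_offset <- function(lp, target) {
  f <- function(off) mean(stats::plogis(lp + off)) - target
  stats::uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
}

#' Schema of the cohort table
#'
#' Machine-readable column descriptor: name, type, units and allowed
#' range for every core column of the cohort CSV.
#'
#' @return data frame with columns \code{column}, \code{type},
#'   \code{units}, \code{range}, \code{required}.
#' @export
cohort_schema <- function() {
  data.frame(
    column = c("patient_id", "age_months", "sex", "heart_rate_bpm",
               "temperature_c", "muac_mm", "spo2_pct",
               "respiratory_rate_bpm", "parent_concern",
               "difficulty_breathing", "oedema", "pallor", "admitted",
               "length_of_stay_hours", "readmitted_within_48h"),
    type = c("string", "real", "categorical", "real", "real", "real",
             "real", "real", "binary", "binary", "binary", "binary",
             "binary", "real", "binary"),
    units = c("", "months", "female/male", "beats/min", "deg C", "mm",
              "percent", "breaths/min", "", "", "", "", "", "hours", ""),
    range = c("", ">=0", "", ">0", "[33,43]", ">0", "[50,100]", ">0",
              "{0,1}", "{0,1}", "{0,1}", "{0,1}", "{0,1}",
              ">=0 or absent when not admitted", "{0,1}"),
    required = TRUE,
    stringsAsFactors = FALSE)
}

#' Write / read a cohort CSV
#'
#' Values round-trip at full double precision; absent values are encoded
#' as empty fields. \code{read_cohort} errors when required schema columns
#' are missing and warns (passing them through) on unknown columns.
#'
#' @param cohort cohort data frame.
#' @param path CSV file path.
#' @param schema for \code{write_cohort}, also write the machine-readable
#'   schema descriptor next to the cohort (\code{<path>.schema.csv}).
#' @return \code{write_cohort} the path, invisibly; \code{read_cohort}
#'   the cohort data frame.
#' @export
write_cohort <- function(cohort, path, schema = FALSE) {
  out <- cohort
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           format(out[[col]], digits = 17, trim = TRUE,
                                  scientific = FALSE))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  if (isTRUE(schema)) {
    utils::write.csv(cohort_schema(), paste0(path, ".schema.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  sch <- cohort_schema()
  required <- setdiff(sch$column, "patient_id")
  miss <- setdiff(required, names(x))
  if (length(miss)) stopf("read_cohort: missing required column(s): %s",
                          paste(miss, collapse = ", "))
  known <- c(sch$column, grep("^noise_[0-9]+$", names(x), value = TRUE),
             "outcome", "sqrt_age", "vs_spo2")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) warnf("read_cohort: unknown column(s) passed through: %s",
                             paste(unknown, collapse = ", "))
  x
}

#' Candidate predictor columns of a cohort
#'
#' The transformed-scale candidate set offered to variable selection: the
#' nine model predictors plus respiratory rate (a decoy the published
#' model does not retain) and any generated noise predictors.
#'
#' @param cohort cohort data frame (transforms applied).
#' @param include_decoys include respiratory rate and noise columns.
#' @return character vector of column names.
#' @export
candidate_predictors <- function(cohort, include_decoys = TRUE) {
  core <- c("sqrt_age", "heart_rate_bpm", "temperature_c", "muac_mm",
            "vs_spo2", "parent_concern", "difficulty_breathing", "oedema",
            "pallor")
  out <- intersect(core, names(cohort))
  if (include_decoys) {
    out <- c(out, intersect("respiratory_rate_bpm", names(cohort)),
             grep("^noise_[0-9]+$", names(cohort), value = TRUE))
  }
  out
}
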