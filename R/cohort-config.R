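#' Synthetic-registry generator configuration
#'
#' Builds the configuration for [generate_cohort()]. The generator emulates a
#' national bronchiectasis registry cohort: blood neutrophils follow a
#' right-skewed lognormal, and every other clinical variable is drawn from a
#' below-threshold marginal, with patients whose neutrophils fall at or above
#' `planted_threshold` receiving a step shift (continuous variables), a second
#' prevalence (binary traits), or a second probability vector (categorical
#' traits). With `planted_threshold = NULL` the cohort is a null model: all
#' patients share the below-threshold marginals and no variable is related to
#' the neutrophil count.
#'
#' Default marginals are calibrated to the below-threshold column of the
#' registry characterization tables (age 67.1 (14.6) years, FEV1 78 (24) %
#' predicted, chronic Pseudomonas colonization 21.5%, ...), and default effect
#' sizes to the above-minus-below differences of the same tables. The default
#' lognormal parameters (meanlog 8.317, sdlog 0.44) put the sub-threshold
#' stratum mean/sd at roughly 3370 (910) cells/uL and ~32.6% of patients above
#' 4990 cells/uL.
#'
#' @param n_patients Number of patients to generate (>= 0).
#' @param seed Integer seed; cohorts are a pure function of (config, seed).
#' @param planted_threshold Neutrophil cut-off in cells/uL at which the step
#'   effect is planted, or `NULL` for the null model.
#' @param neutrophil_log_mean,neutrophil_log_sd Lognormal parameters of the
#'   neutrophil count (cells/uL scale).
#' @param effect_sizes Named list overriding default effects: a single additive
#'   shift for continuous/count variables, a length-2 numeric
#'   `c(below, above)` prevalence pair for binary variables, or a probability
#'   vector (the above-threshold distribution) for categorical variables.
#' @param marginals Named list overriding default below-threshold marginals:
#'   `c(mean, sd)` for continuous variables, a single prevalence for binary
#'   variables, a single rate for count variables, or a probability vector for
#'   categorical variables.
#' @param missingness Named list of per-variable missing-completely-at-random
#'   probabilities.
#' @return A `neutro_config` list, validated.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients,
                          seed = 1L,
                          planted_threshold = 4990,
                          neutrophil_log_mean = 8.317,
                          neutrophil_log_sd = 0.44,
                          effect_sizes = list(),
                          marginals = list(),
                          missingness = NULL) {
  cfg <- list(
    n_patients = n_patients,
    seed = as.integer(seed),
    planted_threshold = planted_threshold,
    neutrophil_log_mean = neutrophil_log_mean,
    neutrophil_log_sd = neutrophil_log_sd,
    marginals = utils::modifyList(default_marginals(), marginals),
    effect_sizes = utils::modifyList(default_effect_sizes(), effect_sizes),
    missingness = missingness %||% default_missingness()
  )
  validate_config(cfg)
  structure(cfg, class = "neutro_config")
}

# Below-threshold marginals: continuous are c(mean, sd); binary a prevalence;
# counts a Poisson rate; categorical a probability vector.
default_marginals <- function() {
  list(
    age = c(67.1, 14.6),
    bmi = c(25.7, 4.9),
    fev1_pct = c(78, 24),
    fvc_pct = c(88, 21),
    fev1_fvc = c(70, 12),
    dlco_pct = c(86, 22),
    pack_years = c(28.2, 24.8),
    lymphocytes = c(2130, 2270),
    eosinophils = c(210, 200),
    platelets = c(239000, 67000),
    crp = c(2.89, 8.54),
    esr = c(16.03, 14.62),
    fibrinogen = c(396.5, 109.5),
    total_protein = c(7.04, 0.59),
    albumin = c(4.23, 0.41),
    wbc_residual = c(570, 250),
    exacerbations_prior_year = 1.5,
    hospitalizations_prior_year = 0.5,
    charlson = 1.8,
    radiological_lobes = 2.88,
    pa_colonization = 0.215,
    other_colonization = 0.25,
    copd = 0.082,
    asthma = 0.10,
    cystic_bronchiectasis = 0.20,
    myocardial_infarction = 0.032,
    heart_failure = 0.060,
    dementia = 0.004,
    diabetes = 0.102,
    kidney_failure = 0.023,
    smoking_status = c(never = 0.64, current = 0.07, ex = 0.29),
    dyspnea_mmrc = c(0.35, 0.30, 0.20, 0.10, 0.05)
  )
}

# Above-minus-below step effects (continuous/count shifts), below/above
# prevalence pairs (binary) and above-threshold probability vectors
# (categorical), calibrated to the above-threshold table columns.
default_effect_sizes <- function() {
  list(
    age = 3.2,
    bmi = 0.5,
    fev1_pct = -14,
    fvc_pct = -9,
    fev1_fvc = -6,
    dlco_pct = -13,
    pack_years = 7.2,
    lymphocytes = -60,
    eosinophils = -30,
    platelets = 38000,
    crp = 2.42,
    esr = 6.24,
    fibrinogen = 104,
    total_protein = -0.15,
    albumin = -0.15,
    exacerbations_prior_year = 0.2,
    hospitalizations_prior_year = 0.6,
    charlson = 0.4,
    radiological_lobes = 0,
    pa_colonization = c(0.215, 0.335),
    other_colonization = c(0.25, 0.25),
    copd = c(0.082, 0.184),
    asthma = c(0.10, 0.107),
    cystic_bronchiectasis = c(0.20, 0.20),
    myocardial_infarction = c(0.032, 0.059),
    heart_failure = c(0.060, 0.131),
    dementia = c(0.004, 0.018),
    diabetes = c(0.102, 0.151),
    kidney_failure = c(0.023, 0.059),
    smoking_status = c(never = 0.48, current = 0.12, ex = 0.40),
    dyspnea_mmrc = c(0.25, 0.27, 0.23, 0.15, 0.10)
  )
}

default_missingness <- function() {
  list(
    dlco_pct = 0.08, pack_years = 0.05, crp = 0.04, esr = 0.04,
    fibrinogen = 0.04, total_protein = 0.03, albumin = 0.03
  )
}

# variable -> sampling family; lower/upper clamps keep physiology plausible
.cont_families <- list(
  age = list(family = "normal", min = 18),
  bmi = list(family = "normal", min = 12),
  fev1_pct = list(family = "normal", min = 10),
  fvc_pct = list(family = "normal", min = 10),
  fev1_fvc = list(family = "normal", min = 15, max = 100),
  dlco_pct = list(family = "normal", min = 10),
  pack_years = list(family = "gamma"),
  lymphocytes = list(family = "gamma"),
  eosinophils = list(family = "gamma"),
  platelets = list(family = "normal", min = 20000),
  crp = list(family = "gamma"),
  esr = list(family = "gamma"),
  fibrinogen = list(family = "normal", min = 50),
  total_protein = list(family = "normal", min = 3),
  albumin = list(family = "normal", min = 1.5),
  wbc_residual = list(family = "normal", min = 0)
)

.count_vars <- c(
  "exacerbations_prior_year", "hospitalizations_prior_year",
  "charlson", "radiological_lobes"
)

.binary_vars <- c(
  "pa_colonization", "other_colonization", "copd", "asthma",
  "cystic_bronchiectasis", "myocardial_infarction", "heart_failure",
  "dementia", "diabetes", "kidney_failure"
)

validate_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid generator configuration: field `%s` %s", field, why),
      call. = FALSE
    )
  }
  if (length(cfg$n_patients) != 1L || is.na(cfg$n_patients) ||
    cfg$n_patients < 0 || cfg$n_patients != floor(cfg$n_patients)) {
    bad("n_patients", "must be a non-negative integer")
  }
  if (!is.null(cfg$planted_threshold) &&
    (!is.finite(cfg$planted_threshold) || cfg$planted_threshold <= 0)) {
    bad("planted_threshold", "must be > 0 when present")
  }
  if (!is.finite(cfg$neutrophil_log_sd) || cfg$neutrophil_log_sd <= 0) {
    bad("neutrophil_log_sd", "must be > 0")
  }
  m <- cfg$marginals
  for (v in names(.cont_families)) {
    if (!is.null(m[[v]])) {
      if (length(m[[v]]) != 2L) bad(v, "continuous marginal needs c(mean, sd)")
      if (!is.finite(m[[v]][2]) || m[[v]][2] <= 0) bad(v, "has sd <= 0")
    }
  }
  for (v in .count_vars) {
    if (!is.null(m[[v]]) && (m[[v]] < 0 || !is.finite(m[[v]]))) {
      bad(v, "count marginal (rate) must be >= 0")
    }
  }
  for (v in .binary_vars) {
    if (!is.null(m[[v]]) && (m[[v]] < 0 || m[[v]] > 1)) {
      bad(v, "prevalence must lie in [0, 1]")
    }
    e <- cfg$effect_sizes[[v]]
    if (!is.null(e) && (length(e) != 2L || any(e < 0) || any(e > 1))) {
      bad(v, "effect must be a below/above prevalence pair in [0, 1]")
    }
  }
  for (v in c("smoking_status", "dyspnea_mmrc")) {
    for (p in list(m[[v]], cfg$effect_sizes[[v]])) {
      if (!is.null(p) && (any(p < 0) || abs(sum(p) - 1) > 1e-8)) {
        bad(v, "probability vector must be non-negative and sum to 1")
      }
    }
  }
  for (v in names(cfg$missingness)) {
    pr <- cfg$missingness[[v]]
    if (pr < 0 || pr > 1) bad(v, "missingness probability must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.neutro_config <- function(x, ...) {
  cat("<neutro_config>\n")
  cat("  n_patients:", x$n_patients, " seed:", x$seed, "\n")
  cat(
    "  planted_threshold:",
    if (is.null(x$planted_threshold)) "none (null model)" else
      paste(x$planted_threshold, "cells/uL"), "\n"
  )
  cat(sprintf(
    "  neutrophils ~ lognormal(meanlog = %.3f, sdlog = %.3f)\n",
    x$neutrophil_log_mean, x$neutrophil_log_sd
  ))
  invisible(x)
}
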