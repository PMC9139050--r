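#' Generate a synthetic registry cohort
#'
#' Draws `config$n_patients` patient records. Neutrophils come first, from the
#' configured lognormal; every other variable is then drawn from its
#' below-threshold marginal, with the configured step effect applied to
#' patients at or above `planted_threshold`. Total leukocytes are not drawn
#' independently: they are assembled as neutrophils + lymphocytes +
#' eosinophils + a non-negative residual (monocytes/basophils), so the
#' additivity invariant `neutrophils <= leukocytes` holds by construction.
#' Missing values are injected per variable, completely at random.
#'
#' The cohort is a pure function of the configuration (which includes the
#' seed): calling twice with the same config yields identical tables. The
#' caller's RNG state is left untouched.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble of class `neutro_cohort`, one row per patient, with a
#'   `provenance` attribute (label + configuration hash).
#' @examples
#' cohort <- generate_cohort(cohort_config(200, seed = 42))
#' dplyr::glimpse(cohort[1:4, 1:8])
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "neutro_config")) {
    config <- do.call(cohort_config, config)
  }
  validate_config(config)
  n <- config$n_patients

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  m <- config$marginals
  eff <- config$effect_sizes

  neutrophils <- stats::rlnorm(
    n, config$neutrophil_log_mean, config$neutrophil_log_sd
  )
  above <- if (is.null(config$planted_threshold)) {
    rep(FALSE, n)
  } else {
    neutrophils >= config$planted_threshold
  }

  draw_cont <- function(v) {
    fam <- .cont_families[[v]]
    mu <- m[[v]][1] + ifelse(above, eff[[v]] %||% 0, 0)
    sd <- m[[v]][2]
    x <- if (fam$family == "gamma") {
      # gamma with per-patient mean, shared shape from the below stratum cv
      shape <- (m[[v]][1] / sd)^2
      mu_pos <- pmax(mu, 1e-6)
      stats::rgamma(n, shape = shape, rate = shape / mu_pos)
    } else {
      stats::rnorm(n, mean = mu, sd = sd)
    }
    if (!is.null(fam$min)) x <- pmax(x, fam$min)
    if (!is.null(fam$max)) x <- pmin(x, fam$max)
    x
  }
  draw_count <- function(v) {
    lam <- pmax(m[[v]] + ifelse(above, eff[[v]] %||% 0, 0), 0)
    stats::rpois(n, lam)
  }
  draw_binary <- function(v) {
    pr <- ifelse(above, eff[[v]][2], eff[[v]][1])
    stats::runif(n) < pr
  }
  draw_categ <- function(v, levels) {
    below_p <- m[[v]]
    above_p <- eff[[v]]
    out <- integer(n)
    if (any(!above)) {
      out[!above] <- sample.int(length(levels), sum(!above),
        replace = TRUE, prob = below_p
      )
    }
    if (any(above)) {
      out[above] <- sample.int(length(levels), sum(above),
        replace = TRUE, prob = above_p
      )
    }
    levels[out]
  }

  rec <- list(patient_id = sprintf("P%05d", seq_len(n)))
  rec$age <- draw_cont("age")
  rec$bmi <- draw_cont("bmi")
  rec$smoking_status <- as.character(
    draw_categ("smoking_status", c("never", "current", "ex"))
  )
  rec$pack_years <- ifelse(rec$smoking_status == "never", 0,
    draw_cont("pack_years")
  )
  rec$fev1_pct <- draw_cont("fev1_pct")
  rec$fvc_pct <- draw_cont("fvc_pct")
  rec$fev1_fvc <- draw_cont("fev1_fvc")
  rec$dlco_pct <- draw_cont("dlco_pct")
  rec$dyspnea_mmrc <- as.integer(draw_categ("dyspnea_mmrc", 0:4))
  # radiological extension: 1..6 affected lobes, truncated shifted Poisson
  lam_lobes <- pmax(m$radiological_lobes +
    ifelse(above, eff$radiological_lobes %||% 0, 0) - 1, 0)
  rec$radiological_lobes <- 1L + pmin(stats::rpois(n, lam_lobes), 5L)
  rec$exacerbations_prior_year <- draw_count("exacerbations_prior_year")
  rec$hospitalizations_prior_year <- draw_count("hospitalizations_prior_year")
  rec$charlson <- draw_count("charlson")
  for (v in .binary_vars) rec[[v]] <- draw_binary(v)

  rec$neutrophils <- neutrophils
  rec$lymphocytes <- draw_cont("lymphocytes")
  rec$eosinophils <- draw_cont("eosinophils")
  residual <- draw_cont("wbc_residual")
  rec$leukocytes <- rec$neutrophils + rec$lymphocytes +
    rec$eosinophils + residual
  rec$platelets <- draw_cont("platelets")
  rec$crp <- draw_cont("crp")
  rec$esr <- draw_cont("esr")
  rec$fibrinogen <- draw_cont("fibrinogen")
  rec$total_protein <- draw_cont("total_protein")
  rec$albumin <- draw_cont("albumin")

  cohort <- tibble::as_tibble(rec)

  for (v in names(config$missingness)) {
    if (!v %in% names(cohort)) next
    pr <- config$missingness[[v]]
    if (pr > 0) cohort[[v]][stats::runif(n) < pr] <- NA
  }

  new_cohort(cohort,
    label = sprintf(
      "synthetic registry cohort (n = %d, seed = %d)", n, config$seed
    ),
    config_hash = hash_config(unclass(config))
  )
}

new_cohort <- function(data, label = "cohort", config_hash = NA_character_) {
  if (anyDuplicated(data$patient_id)) {
    stop("patient_id must be unique within a cohort", call. = FALSE)
  }
  structure(
    data,
    provenance = list(label = label, config_hash = config_hash),
    class = c("neutro_cohort", class(tibble::as_tibble(data)))
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Cohort provenance
#'
#' @param cohort A `neutro_cohort`.
#' @return The provenance list (label, configuration hash).
#' @export
cohort_provenance <- function(cohort) attr(cohort, "provenance")
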