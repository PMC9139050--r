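#' Read / write a cohort CSV
#'
#' Cohort files are UTF-8 CSV with a header row; missing values are empty
#' cells. Floating-point values round-trip at full double precision. Unknown
#' columns are kept (with a warning) so site-specific extras such as centre
#' codes pass through untouched; malformed rows abort with the offending line
#' number.
#'
#' @param cohort A cohort tibble (e.g. from [generate_cohort()]).
#' @param path File path.
#' @return `read_cohort()` returns a `neutro_cohort` tibble;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

# expected column -> readr type; everything else passes through as guessed
.cohort_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    smoking_status = readr::col_character(),
    dyspnea_mmrc = readr::col_integer(),
    radiological_lobes = readr::col_integer(),
    exacerbations_prior_year = readr::col_integer(),
    hospitalizations_prior_year = readr::col_integer(),
    charlson = readr::col_integer(),
    .default = readr::col_guess()
  )
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  data <- readr::read_csv(
    path,
    na = "", col_types = .cohort_col_types(),
    show_col_types = FALSE, progress = FALSE
  )
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    stop(sprintf(
      "malformed cohort file `%s`: %s at line %d",
      path, probs$expected[1], probs$row[1]
    ), call. = FALSE)
  }
  known <- c(
    "patient_id", "age", "bmi", "smoking_status", "pack_years",
    "fev1_pct", "fvc_pct", "fev1_fvc", "dlco_pct", "dyspnea_mmrc",
    "radiological_lobes", "exacerbations_prior_year",
    "hospitalizations_prior_year", "charlson", .binary_vars,
    "neutrophils", "lymphocytes", "eosinophils", "leukocytes",
    "platelets", "crp", "esr", "fibrinogen", "total_protein", "albumin",
    "faced", "efaced", "bsi", "faced_cat", "efaced_cat", "bsi_cat"
  )
  extra <- setdiff(names(data), known)
  if (length(extra) > 0) {
    warning(
      "unknown cohort column(s) kept as pass-through: ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(data$patient_id)) {
    data$patient_id <- sprintf("P%05d", seq_len(nrow(data)))
  }
  new_cohort(data, label = paste0("read from ", path))
}
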