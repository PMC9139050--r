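#' Pooled-variance Student's t test
#'
#' Two-sided Student's t with pooled variance on `n_a + n_b - 2` degrees of
#' freedom (the classical "T-student" of clinical tables; Welch is available
#' via `pooled = FALSE`). Degenerate convention when the pooled variance is
#' zero: identical means give p = 1, different means p = 0.
#'
#' @param sample_a,sample_b Numeric vectors, each with >= 2 non-missing
#'   values.
#' @param pooled Use the pooled-variance statistic (default) or Welch.
#' @return A `neutro_test`.
#' @export
student_t <- function(sample_a, sample_b, pooled = TRUE) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  n_a <- length(a)
  n_b <- length(b)
  if (n_a < 2L || n_b < 2L) {
    stop("each sample needs >= 2 non-missing values", call. = FALSE)
  }
  d <- mean(a) - mean(b)
  if (pooled) {
    s2 <- ((n_a - 1) * stats::var(a) + (n_b - 1) * stats::var(b)) /
      (n_a + n_b - 2)
    if (s2 <= 0) {
      return(new_test_result(
        ifelse(d == 0, 0, sign(d) * Inf), ifelse(d == 0, 1, 0),
        "Student t (pooled)", n_a, n_b,
        note = "degenerate: zero pooled variance"
      ))
    }
    tstat <- d / sqrt(s2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
    method <- "Student t (pooled)"
  } else {
    va <- stats::var(a) / n_a
    vb <- stats::var(b) / n_b
    if (va + vb <= 0) {
      return(new_test_result(
        ifelse(d == 0, 0, sign(d) * Inf), ifelse(d == 0, 1, 0),
        "Welch t", n_a, n_b,
        note = "degenerate: zero variance"
      ))
    }
    tstat <- d / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    method <- "Welch t"
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  new_test_result(tstat, p, method, n_a, n_b)
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' Pearson's statistic without continuity correction by default (set
#' `correct = TRUE` for the Yates-corrected 2 x 2 version); df = k - 1.
#' Warns when any expected count is below 5.
#'
#' @param table Matrix of non-negative counts, 2 rows (groups) x k columns
#'   (categories); both margins must be positive.
#' @param correct Apply the Yates continuity correction (2 x 2 only).
#' @return A `neutro_test` (`n_a`, `n_b` are the row totals).
#' @export
chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || nrow(table) != 2L) {
    stop("need a 2 x k matrix of non-negative counts", call. = FALSE)
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("chi-square undefined: a margin is zero", call. = FALSE)
  }
  n <- sum(table)
  expected <- outer(rs, cs) / n
  note <- NULL
  if (any(expected < 5)) {
    note <- "some expected counts < 5; chi-square approximation is doubtful"
    warning(note, call. = FALSE)
  }
  dev <- abs(table - expected)
  if (correct && ncol(table) == 2L) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- ncol(table) - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  new_test_result(stat, p, sprintf("Pearson chi-square (df = %d)", df),
    rs[1], rs[2],
    note = note
  )
}

#' Variable specification for comparison tables
#'
#' @param name Column name in the cohort.
#' @param kind `"continuous"`, `"binary"` or `"categorical"` — determines the
#'   test (t vs chi-square) and the summary style (mean (SD) vs N (%)).
#' @param units Display units.
#' @param section Table section label.
#' @return A one-row tibble.
#' @export
variable_spec <- function(name, kind = c("continuous", "binary", "categorical"),
                          units = "", section = "") {
  kind <- match.arg(kind)
  tibble::tibble(name = name, kind = kind, units = units, section = section)
}

#' Default registry table layout
#'
#' The variable list of the cohort characterization tables: anthropometry,
#' severity, smoking, lung function, blood analytes and comorbidities.
#'
#' @return A tibble of [variable_spec()] rows.
#' @export
default_variable_specs <- function() {
  dplyr::bind_rows(
    variable_spec("age", "continuous", "years", "anthropometric"),
    variable_spec("bmi", "continuous", "kg/m2", "anthropometric"),
    variable_spec("faced", "continuous", "points", "severity"),
    variable_spec("efaced", "continuous", "points", "severity"),
    variable_spec("bsi", "continuous", "points", "severity"),
    variable_spec(
      "exacerbations_prior_year", "continuous", "count", "severity"
    ),
    variable_spec(
      "hospitalizations_prior_year", "continuous", "count", "severity"
    ),
    variable_spec("charlson", "continuous", "points", "severity"),
    variable_spec("radiological_lobes", "continuous", "lobes", "severity"),
    variable_spec("pa_colonization", "binary", "", "severity"),
    variable_spec("asthma", "binary", "", "severity"),
    variable_spec("copd", "binary", "", "severity"),
    variable_spec("smoking_status", "categorical", "", "smoking"),
    variable_spec("pack_years", "continuous", "pack-years", "smoking"),
    variable_spec("fev1_pct", "continuous", "% predicted", "lung function"),
    variable_spec("fvc_pct", "continuous", "% predicted", "lung function"),
    variable_spec("fev1_fvc", "continuous", "%", "lung function"),
    variable_spec("dlco_pct", "continuous", "% predicted", "lung function"),
    variable_spec("leukocytes", "continuous", "cells/uL", "blood"),
    variable_spec("neutrophils", "continuous", "cells/uL", "blood"),
    variable_spec("lymphocytes", "continuous", "cells/uL", "blood"),
    variable_spec("eosinophils", "continuous", "cells/uL", "blood"),
    variable_spec("platelets", "continuous", "cells/uL", "blood"),
    variable_spec("crp", "continuous", "mg/dL", "blood"),
    variable_spec("esr", "continuous", "mm/h", "blood"),
    variable_spec("fibrinogen", "continuous", "mg/dL", "blood"),
    variable_spec("total_protein", "continuous", "g/dL", "blood"),
    variable_spec("albumin", "continuous", "g/dL", "blood"),
    variable_spec("myocardial_infarction", "binary", "", "comorbidity"),
    variable_spec("heart_failure", "binary", "", "comorbidity"),
    variable_spec("dementia", "binary", "", "comorbidity"),
    variable_spec("diabetes", "binary", "", "comorbidity"),
    variable_spec("kidney_failure", "binary", "", "comorbidity")
  )
}

#' Two-cluster characterization table
#'
#' One row per variable (binary/continuous) or per level (categorical), with
#' below- and above-cluster summaries, the appropriate test and significance
#' stars. Continuous variables are summarized as mean (SD) and compared with
#' the pooled t test; binary and categorical variables as N (%) with
#' Pearson's chi-square. Missing data are handled pairwise: each row uses all
#' patients non-missing for that variable. An optional exclusion flag
#' (e.g. `"copd"`, `"pa_colonization"`) drops flagged patients before any
#' summary, reproducing the subgroup re-analyses; percent denominators are
#' the post-exclusion group sizes.
#'
#' @param cohort Cohort data frame (scored, if severity rows are requested).
#' @param assignment A [dichotomize()] assignment covering the cohort.
#' @param specs Variable specifications
#'   (default [default_variable_specs()], restricted to available columns).
#' @param exclusion Optional name of a logical column; flagged patients are
#'   excluded.
#' @param pooled Pooled t (default) vs Welch.
#' @param correct Yates correction for 2 x 2 chi-square (default off).
#' @return A `neutro_comparison` tibble: variable, level, kind, summaries
#'   (mean/sd or count/percent per cluster), n per cluster, test statistic,
#'   p, stars. Attributes: `group_sizes`, `exclusion`.
#' @export
comparison_table <- function(cohort, assignment, specs = NULL,
                             exclusion = NULL, pooled = TRUE,
                             correct = FALSE) {
  specs <- specs %||%
    dplyr::filter(default_variable_specs(), .data$name %in% names(cohort))
  missing_cols <- setdiff(specs$name, names(cohort))
  if (length(missing_cols) > 0) {
    stop(
      "variable spec names absent from cohort: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  data <- dplyr::left_join(cohort, assignment, by = "patient_id")
  if (!is.null(exclusion)) {
    if (!exclusion %in% names(data)) {
      stop("exclusion flag column not found: ", exclusion, call. = FALSE)
    }
    data <- data[!is.na(data[[exclusion]]) & !data[[exclusion]], ]
  }
  data <- data[data$cluster %in% c("below", "above"), ]
  below <- data[data$cluster == "below", ]
  above <- data[data$cluster == "above", ]

  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    v <- specs$name[i]
    kind <- specs$kind[i]
    rows[[i]] <- switch(kind,
      continuous = comparison_row_continuous(v, below[[v]], above[[v]], pooled),
      binary = comparison_row_binary(v, below[[v]], above[[v]], correct),
      categorical = comparison_row_categorical(v, below[[v]], above[[v]])
    )
  }
  out <- dplyr::bind_rows(rows)
  out$stars <- stars(out$p)
  structure(
    out,
    group_sizes = c(below = nrow(below), above = nrow(above)),
    exclusion = exclusion %||% "none",
    class = c("neutro_comparison", class(tibble::tibble()))
  )
}

comparison_row_continuous <- function(v, x_below, x_above, pooled) {
  test <- student_t(x_above, x_below, pooled = pooled)
  tibble::tibble(
    variable = v, level = NA_character_, kind = "continuous",
    below_mean = mean(x_below, na.rm = TRUE),
    below_sd = stats::sd(x_below, na.rm = TRUE),
    below_count = NA_integer_, below_pct = NA_real_,
    above_mean = mean(x_above, na.rm = TRUE),
    above_sd = stats::sd(x_above, na.rm = TRUE),
    above_count = NA_integer_, above_pct = NA_real_,
    n_below = sum(!is.na(x_below)), n_above = sum(!is.na(x_above)),
    statistic = test$statistic, p = test$p_value
  )
}

comparison_row_binary <- function(v, x_below, x_above, correct) {
  x_below <- x_below[!is.na(x_below)]
  x_above <- x_above[!is.na(x_above)]
  tab <- rbind(
    below = c(sum(x_below), sum(!x_below)),
    above = c(sum(x_above), sum(!x_above))
  )
  test <- tryCatch(
    suppressWarnings(chi_square(tab, correct = correct)),
    error = function(e) new_test_result(NA_real_, NA_real_, "chi-square",
      length(x_below), length(x_above),
      note = conditionMessage(e)
    )
  )
  tibble::tibble(
    variable = v, level = NA_character_, kind = "binary",
    below_mean = NA_real_, below_sd = NA_real_,
    below_count = sum(x_below),
    below_pct = percentage(sum(x_below), max(length(x_below), 1L), 1),
    above_mean = NA_real_, above_sd = NA_real_,
    above_count = sum(x_above),
    above_pct = percentage(sum(x_above), max(length(x_above), 1L), 1),
    n_below = length(x_below), n_above = length(x_above),
    statistic = test$statistic, p = test$p_value
  )
}

comparison_row_categorical <- function(v, x_below, x_above) {
  x_below <- x_below[!is.na(x_below)]
  x_above <- x_above[!is.na(x_above)]
  levels <- sort(unique(c(x_below, x_above)))
  tab <- rbind(
    below = vapply(levels, function(l) sum(x_below == l), integer(1)),
    above = vapply(levels, function(l) sum(x_above == l), integer(1))
  )
  test <- tryCatch(
    suppressWarnings(chi_square(tab)),
    error = function(e) new_test_result(NA_real_, NA_real_, "chi-square",
      length(x_below), length(x_above),
      note = conditionMessage(e)
    )
  )
  # one row per level; the omnibus test is repeated across the block
  dplyr::bind_rows(lapply(levels, function(l) {
    tibble::tibble(
      variable = v, level = as.character(l), kind = "categorical",
      below_mean = NA_real_, below_sd = NA_real_,
      below_count = sum(x_below == l),
      below_pct = percentage(sum(x_below == l), max(length(x_below), 1L), 1),
      above_mean = NA_real_, above_sd = NA_real_,
      above_count = sum(x_above == l),
      above_pct = percentage(sum(x_above == l), max(length(x_above), 1L), 1),
      n_below = length(x_below), n_above = length(x_above),
      statistic = test$statistic, p = test$p_value
    )
  }))
}

#' Render a comparison table in printed style
#'
#' Formats mean (SD) / N (%) cells at table precision (1 decimal, half-up)
#' with exact p and stars, in the printed column order.
#'
#' @param comparison A `neutro_comparison`.
#' @return A character-cell tibble ready for CSV or Markdown export.
#' @export
format_comparison <- function(comparison) {
  fmt1 <- function(x) format(round_half_up(x, 1), trim = TRUE, nsmall = 1)
  cell <- function(kind, m, s, cnt, pct) {
    ifelse(kind == "continuous",
      sprintf("%s (%s)", fmt1(m), fmt1(s)),
      sprintf("%d (%s)", cnt, fmt1(pct))
    )
  }
  tibble::tibble(
    variable = ifelse(is.na(comparison$level), comparison$variable,
      paste0(comparison$variable, ": ", comparison$level)
    ),
    below = cell(
      comparison$kind, comparison$below_mean, comparison$below_sd,
      comparison$below_count, comparison$below_pct
    ),
    above = cell(
      comparison$kind, comparison$above_mean, comparison$above_sd,
      comparison$above_count, comparison$above_pct
    ),
    p = signif(comparison$p, 3),
    stars = comparison$stars
  )
}

#' Export a comparison table
#'
#' @param comparison A `neutro_comparison`.
#' @param path Output file; `format = "csv"` writes the full-precision table,
#'   `"markdown"` the printed-style cells.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(tibble::as_tibble(comparison), path, na = "")
  } else {
    f <- format_comparison(comparison)
    lines <- c(
      paste0("| ", paste(names(f), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(f)), collapse = "|"), "|"),
      apply(f, 1, function(r) {
        paste0("| ", paste(ifelse(is.na(r), "", r), collapse = " | "), " |")
      })
    )
    writeLines(lines, path)
  }
  invisible(path)
}
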