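#' Score a cohort against a point table
#'
#' Evaluates every component of `table` over the rows of `data`. A component
#' whose input is missing contributes no points and renders that patient's
#' total undefined (`NA`): severity is never imputed. Inputs are validated
#' first (dyspnea grade must be an integer 0-4, percentages and counts
#' non-negative); out-of-range values abort.
#'
#' @param data A cohort data frame (one row per patient).
#' @param table A `neutro_point_table`.
#' @return A list with `points` (patients x components integer matrix, `NA`
#'   where an input was missing) and `total` (integer vector, `NA` when any
#'   component was missing).
#' @seealso [score_breakdown()] for a single-patient view,
#'   [score_cohort()] to append all three index columns.
#' @export
compute_scores <- function(data, table) {
  stopifnot(inherits(table, "neutro_point_table"))
  validate_score_inputs(data)
  n <- nrow(data)
  comps <- table$components
  pts <- matrix(NA_integer_,
    nrow = n, ncol = length(comps),
    dimnames = list(NULL, vapply(comps, `[[`, "", "name"))
  )
  for (j in seq_along(comps)) {
    pts[, j] <- component_points(data, comps[[j]])
  }
  total <- as.integer(rowSums(pts))
  list(points = pts, total = total)
}

component_points <- function(data, comp) {
  field <- need_field(data, comp$field)
  x <- data[[comp$field]]
  out <- switch(comp$type,
    cut = {
      idx <- rep(1L, length(x))
      for (i in seq_along(comp$breaks)) {
        past <- if (comp$left_open[i]) x > comp$breaks[i] else
          x >= comp$breaks[i]
        idx <- idx + as.integer(past)
      }
      comp$points[idx]
    },
    flag = ifelse(as.logical(x), comp$points, 0L),
    ge_or_flag = {
      flag <- need_field(data, comp$flag_field)
      f <- as.logical(data[[comp$flag_field]])
      hit <- (x >= comp$ge) | f
      # one informative input suffices to award; both missing -> missing
      hit[is.na(hit)] <- FALSE
      hit[(is.na(x) & is.na(f))] <- NA
      ifelse(hit, comp$points, 0L)
    },
    stop("unknown component type: ", comp$type, call. = FALSE)
  )
  as.integer(out)
}

need_field <- function(data, field) {
  if (!field %in% names(data)) {
    stop(sprintf("cohort is missing scoring input column `%s`", field),
      call. = FALSE
    )
  }
  invisible(field)
}

validate_score_inputs <- function(data) {
  mm <- data$dyspnea_mmrc
  if (!is.null(mm) && any(!is.na(mm) & !(mm %in% 0:4))) {
    stop("dyspnea_mmrc grades must lie in 0..4", call. = FALSE)
  }
  for (v in c("fev1_pct", "fvc_pct", "age", "bmi")) {
    if (!is.null(data[[v]]) && any(!is.na(data[[v]]) & data[[v]] < 0)) {
      stop(sprintf("`%s` must be non-negative", v), call. = FALSE)
    }
  }
  for (v in c(
    "radiological_lobes", "exacerbations_prior_year",
    "hospitalizations_prior_year"
  )) {
    x <- data[[v]]
    if (!is.null(x) && any(!is.na(x) & (x < 0 | x != floor(x)))) {
      stop(sprintf("`%s` must be a non-negative integer count", v),
        call. = FALSE
      )
    }
  }
  invisible(data)
}

#' Per-patient score breakdown
#'
#' @param record A one-row data frame (a single patient).
#' @param table A `neutro_point_table`.
#' @return A `neutro_score_breakdown`: scale, named per-component points,
#'   `missing_components`, and `total` (`NA` unless all components scored).
#' @examples
#' rec <- data.frame(
#'   fev1_pct = 90, age = 40, pa_colonization = FALSE,
#'   radiological_lobes = 1L, dyspnea_mmrc = 0L
#' )
#' score_breakdown(rec, default_point_tables()$faced)
#' @export
score_breakdown <- function(record, table) {
  stopifnot(nrow(record) == 1L)
  sc <- compute_scores(record, table)
  pts <- sc$points[1, ]
  structure(
    list(
      scale = table$scale,
      points = pts,
      missing_components = names(pts)[is.na(pts)],
      total = sc$total[1]
    ),
    class = "neutro_score_breakdown"
  )
}

#' @export
print.neutro_score_breakdown <- function(x, ...) {
  cat(sprintf("<%s breakdown>\n", x$scale))
  for (nm in names(x$points)) {
    cat(sprintf(
      "  %-18s %s\n", nm,
      ifelse(is.na(x$points[nm]), "missing", x$points[nm])
    ))
  }
  cat(
    "  total:",
    if (is.na(x$total)) "undefined (missing components)" else x$total, "\n"
  )
  invisible(x)
}

#' Append severity scores and categories to a cohort
#'
#' Adds `faced`, `efaced`, `bsi` totals and `faced_cat`, `efaced_cat`,
#' `bsi_cat` mild/moderate/severe categories.
#'
#' @param cohort Cohort data frame.
#' @param tables Point tables as from [default_point_tables()].
#' @return The cohort with six added columns.
#' @export
score_cohort <- function(cohort, tables = default_point_tables()) {
  cohort$faced <- compute_scores(cohort, tables$faced)$total
  cohort$efaced <- compute_scores(cohort, tables$efaced)$total
  cohort$bsi <- compute_scores(cohort, tables$bsi)$total
  cohort$faced_cat <- categorize(cohort$faced, "FACED")
  cohort$efaced_cat <- categorize(cohort$efaced, "EFACED")
  cohort$bsi_cat <- categorize(cohort$bsi, "BSI")
  cohort
}

.category_bounds <- list(
  FACED = list(range = c(0L, 7L), moderate = 3L, severe = 5L),
  EFACED = list(range = c(0L, 9L), moderate = 4L, severe = 7L),
  BSI = list(range = c(0L, 26L), moderate = 5L, severe = 9L)
)

#' Severity category from a score total
#'
#' Interval boundaries follow the published convention used by the registry
#' analysis: FACED mild 0-2, moderate 3-4, severe 5-7; E-FACED mild 0-3,
#' moderate 4-6, severe 7-9; BSI mild 0-4, moderate 5-8, severe >= 9.
#'
#' @param total Integer score total(s); `NA` passes through.
#' @param scale `"FACED"`, `"EFACED"` or `"BSI"`.
#' @return Ordered factor with levels mild < moderate < severe.
#' @examples
#' categorize(5, "FACED") # severe
#' categorize(4, "EFACED") # moderate
#' @export
categorize <- function(total, scale = c("FACED", "EFACED", "BSI")) {
  scale <- match.arg(scale)
  b <- .category_bounds[[scale]]
  ok <- is.na(total) |
    (total >= b$range[1] & total <= b$range[2] & total == floor(total))
  if (!all(ok)) {
    stop(sprintf(
      "%s total outside the %d..%d scale range", scale, b$range[1], b$range[2]
    ), call. = FALSE)
  }
  lab <- ifelse(total >= b$severe, "severe",
    ifelse(total >= b$moderate, "moderate", "mild")
  )
  factor(lab, levels = c("mild", "moderate", "severe"), ordered = TRUE)
}

#' Dichotomize a score total at a cut-off
#'
#' `TRUE` iff `total >= cutoff`; the severe-disease outcomes of the registry
#' analysis are FACED >= 5 and E-FACED >= 7.
#'
#' @param total Integer score total(s).
#' @param scale Scale name (range validation only).
#' @param cutoff Integer cut-off within the scale range.
#' @return Logical vector (`NA` where `total` is `NA`).
#' @export
dichotomize_score <- function(total, scale = c("FACED", "EFACED", "BSI"),
                              cutoff) {
  scale <- match.arg(scale)
  b <- .category_bounds[[scale]]
  if (cutoff < b$range[1] || cutoff > b$range[2]) {
    stop(sprintf(
      "cutoff %s outside the %s range %d..%d",
      format(cutoff), scale, b$range[1], b$range[2]
    ), call. = FALSE)
  }
  if (any(!is.na(total) & (total < b$range[1] | total > b$range[2]))) {
    stop(sprintf("%s total outside the scale range", scale), call. = FALSE)
  }
  total >= cutoff
}
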