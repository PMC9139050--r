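#' Sweep candidate neutrophil cut-offs
#'
#' For every candidate threshold `t`, splits the cohort at neutrophils >= `t`
#' and records the Mann-Whitney p-value for the FACED and E-FACED totals
#' between the two sides, together with the group sizes. Candidates leaving
#' fewer than two patients on either side are recorded with `NA` p-values.
#' P-values are raw: no multiple-testing correction is applied across the
#' grid (matching the registry analysis), which is why downstream selection
#' is known to carry minimum-p selection bias.
#'
#' @param cohort Cohort data frame with a `neutrophils` column (cells/uL).
#'   If `faced` / `efaced` columns are absent the cohort is scored with the
#'   default point tables first.
#' @param grid Candidate thresholds (cells/uL). Default: every `grid_step`
#'   cells/uL from the 5th to the 95th percentile of the observed
#'   neutrophils.
#' @param grid_step Grid spacing in cells/uL (default 10).
#' @param quantile_range Quantiles bounding the default grid.
#' @param alpha Significance level carried into selection (default 0.05).
#' @return A `neutro_scan`: list with `table` (tibble: threshold, p_faced,
#'   p_efaced, n_above, n_below), `alpha`, `n_total`, and later `selected` /
#'   `strategy` once [select_threshold()] has run.
#' @export
scan_thresholds <- function(cohort, grid = NULL, grid_step = 10,
                            quantile_range = c(0.05, 0.95), alpha = 0.05) {
  if (!"neutrophils" %in% names(cohort)) {
    stop("cohort has no `neutrophils` column", call. = FALSE)
  }
  if (!all(c("faced", "efaced") %in% names(cohort))) {
    cohort <- score_cohort(cohort)
  }
  keep <- !is.na(cohort$neutrophils) & !is.na(cohort$faced) &
    !is.na(cohort$efaced)
  neut <- cohort$neutrophils[keep]
  faced <- cohort$faced[keep]
  efaced <- cohort$efaced[keep]
  n <- length(neut)

  if (is.null(grid)) {
    if (n < 4L) stop("too few complete records to build a grid", call. = FALSE)
    q <- stats::quantile(neut, quantile_range, names = FALSE)
    grid <- seq(
      ceiling(q[1] / grid_step) * grid_step, q[2],
      by = grid_step
    )
  }
  if (length(grid) == 0L) stop("empty threshold grid", call. = FALSE)
  grid <- sort(unique(grid))

  p_faced <- p_efaced <- rep(NA_real_, length(grid))
  n_above <- n_below <- integer(length(grid))
  for (i in seq_along(grid)) {
    above <- neut >= grid[i]
    n_above[i] <- sum(above)
    n_below[i] <- n - n_above[i]
    if (n_above[i] < 2L || n_below[i] < 2L) next
    p_faced[i] <- mann_whitney_u(faced[above], faced[!above])$p_value
    p_efaced[i] <- mann_whitney_u(efaced[above], efaced[!above])$p_value
  }

  structure(
    list(
      table = tibble::tibble(
        threshold = grid, p_faced = p_faced, p_efaced = p_efaced,
        n_above = n_above, n_below = n_below
      ),
      alpha = alpha, n_total = n, selected = NULL, strategy = NULL
    ),
    class = "neutro_scan"
  )
}

#' @export
print.neutro_scan <- function(x, ...) {
  cat(sprintf(
    "<threshold scan> %d candidates over %d patients (alpha = %g)\n",
    nrow(x$table), x$n_total, x$alpha
  ))
  if (!is.null(x$selected)) {
    cat(sprintf(
      "  selected: %g cells/uL (strategy %s)\n", x$selected, x$strategy
    ))
  }
  print(x$table, n = 5)
  invisible(x)
}

#' Select the operating threshold from a scan
#'
#' A candidate is eligible when both scores separate significantly
#' (`p_faced < alpha` and `p_efaced < alpha`) and neither cluster falls
#' below `min_fraction` of the cohort. Among eligible candidates:
#'
#' * `"most_balanced"` (default): maximize `min(n_above, n_below)`, i.e. the
#'   most balanced cluster sizes; ties go to the higher threshold.
#' * `"highest_significant"`: the largest eligible threshold.
#' * `"min_p"`: minimize `max(p_faced, p_efaced)` (the classical minimum
#'   p-value cut-point rule; the one that recovers a planted change-point);
#'   ties go to the higher threshold.
#'
#' Returns `NULL` when no candidate is eligible. The result is invariant to
#' grid ordering and duplicated candidates.
#'
#' @param scan A `neutro_scan`.
#' @param strategy Selection strategy label.
#' @param alpha Significance level (defaults to the scan's).
#' @param min_fraction Minimum fraction of patients allowed in the smaller
#'   cluster (default 0.25; the registry split was 337/1034 ~ 33%).
#' @return Selected threshold (cells/uL) or `NULL`.
#' @export
select_threshold <- function(scan,
                             strategy = c(
                               "most_balanced", "highest_significant", "min_p"
                             ),
                             alpha = NULL, min_fraction = 0.25) {
  if (is.character(strategy) && length(strategy) == 1L &&
    !strategy %in% c("most_balanced", "highest_significant", "min_p")) {
    stop("unknown selection strategy: ", strategy, call. = FALSE)
  }
  strategy <- match.arg(strategy)
  alpha <- alpha %||% scan$alpha
  tab <- dplyr::distinct(scan$table)
  balance <- pmin(tab$n_above, tab$n_below)
  eligible <- !is.na(tab$p_faced) & !is.na(tab$p_efaced) &
    tab$p_faced < alpha & tab$p_efaced < alpha &
    balance / scan$n_total >= min_fraction
  if (!any(eligible)) {
    return(NULL)
  }
  tab <- tab[eligible, ]
  balance <- balance[eligible]
  pick <- switch(strategy,
    most_balanced = {
      best <- balance == max(balance)
      max(tab$threshold[best])
    },
    highest_significant = max(tab$threshold),
    min_p = {
      worst_p <- pmax(tab$p_faced, tab$p_efaced)
      best <- worst_p == min(worst_p)
      max(tab$threshold[best])
    }
  )
  pick
}

#' Assign patients to neutrophil clusters
#'
#' Above-threshold membership is inclusive (neutrophils >= threshold, the
#' ">= 4.99 x 10^3 cells/uL" table convention); patients with missing
#' neutrophils are `unassigned`.
#'
#' @param cohort Cohort data frame.
#' @param threshold Cut-off in cells/uL (> 0).
#' @return A `neutro_assignment` tibble: `patient_id`, `cluster` (factor
#'   below/above/unassigned), with the threshold as attribute.
#' @examples
#' coh <- data.frame(patient_id = c("a", "b", "c"), neutrophils = c(4990, 4989.9, NA))
#' dichotomize(coh, 4990)$cluster
#' @export
dichotomize <- function(cohort, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  cl <- ifelse(is.na(cohort$neutrophils), "unassigned",
    ifelse(cohort$neutrophils >= threshold, "above", "below")
  )
  structure(
    tibble::tibble(
      patient_id = cohort$patient_id,
      cluster = factor(cl, levels = c("below", "above", "unassigned"))
    ),
    threshold = threshold,
    class = c("neutro_assignment", class(tibble::tibble()))
  )
}
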