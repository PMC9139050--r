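#' Pearson correlation with t-based p-value
#'
#' Sample Pearson r over complete pairs; two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (perfect correlation gives p = 0). Spearman is available for ordinal
#' variables such as score totals.
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs are dropped.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list with `r`, `p`, `n`.
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)) # r = 0.8
#' @export
pearson <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop("correlation needs >= 3 complete pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: an input is constant", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  r <- stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Pairwise correlation matrix over cohort variables
#'
#' Pairwise complete-case Pearson (or Spearman) correlations between the
#' requested variables, overall or within one neutrophil cluster. Entries
#' with p > 0.05 are reported but flagged in the `masked` matrix, mirroring
#' the crossed-out dots of a corrplot-style display.
#'
#' @param cohort Cohort data frame (scored, for score variables).
#' @param variables Variable names; default follows the registry figure:
#'   severity scores, exacerbation counts, spirometry and neutrophils.
#' @param assignment Optional [dichotomize()] assignment when `subset` is a
#'   cluster name.
#' @param subset `"all"` (default), `"above"` or `"below"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `neutro_cormat`: list of matrices `r`, `p`, `n`, `masked`
#'   (logical, p > 0.05 off-diagonal), plus the subset label.
#' @export
correlation_matrix <- function(cohort,
                               variables = c(
                                 "faced", "efaced", "bsi",
                                 "exacerbations_prior_year",
                                 "hospitalizations_prior_year",
                                 "fev1_pct", "fvc_pct", "fev1_fvc",
                                 "neutrophils"
                               ),
                               assignment = NULL,
                               subset = c("all", "above", "below"),
                               method = c("pearson", "spearman")) {
  subset <- match.arg(subset)
  method <- match.arg(method)
  missing_cols <- setdiff(variables, names(cohort))
  if (length(missing_cols) > 0) {
    stop(
      "variables absent from cohort: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  data <- cohort
  if (subset != "all") {
    if (is.null(assignment)) {
      stop("cluster subset requires an assignment", call. = FALSE)
    }
    keep <- assignment$patient_id[assignment$cluster == subset]
    data <- data[data$patient_id %in% keep, ]
  }
  if (nrow(data) < 3L) {
    stop("subset has fewer than 3 patients", call. = FALSE)
  }
  k <- length(variables)
  r <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  n <- matrix(nrow(data), k, k)
  dimnames(r) <- dimnames(p) <- dimnames(n) <- list(variables, variables)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      res <- pearson(data[[variables[i]]], data[[variables[j]]],
        method = method
      )
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
      n[i, j] <- n[j, i] <- res$n
    }
  }
  diag(n) <- colSums(!is.na(data[variables]))
  masked <- !is.na(p) & p > 0.05
  structure(
    list(
      variables = variables, r = r, p = p, n = n, masked = masked,
      subset = subset, method = method
    ),
    class = "neutro_cormat"
  )
}

#' @export
print.neutro_cormat <- function(x, ...) {
  cat(sprintf(
    "<correlation matrix> %d variables, subset = %s (%s)\n",
    length(x$variables), x$subset, x$method
  ))
  print(round(x$r, 2))
  invisible(x)
}

#' Export a correlation matrix as CSV
#'
#' Writes long-format rows (var_a, var_b, r, p, n, masked).
#'
#' @param cormat A `neutro_cormat`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(cormat, path) {
  k <- length(cormat$variables)
  idx <- which(upper.tri(cormat$r), arr.ind = TRUE)
  readr::write_csv(tibble::tibble(
    var_a = cormat$variables[idx[, 1]],
    var_b = cormat$variables[idx[, 2]],
    r = cormat$r[idx],
    p = cormat$p[idx],
    n = cormat$n[idx],
    masked = cormat$masked[idx]
  ), path, na = "")
  invisible(path)
}
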