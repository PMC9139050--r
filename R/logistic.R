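#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald inference, written for the
#' adjusted cluster-association models. Rows with any missing value are
#' dropped (complete cases; the count is reported). Convergence is declared
#' when the largest score component `|X'(y - p)|` falls below `1e-8`, with a
#' cap of 100 iterations; step-halving keeps the deviance non-increasing at
#' every step. Quasi-separation is flagged when any coefficient exceeds 15 in
#' absolute value — estimates are still reported, with a warning, since
#' perfectly separated data drive the MLE to infinity.
#'
#' @param outcome Binary vector (logical or 0/1); both classes required.
#' @param design Data frame or matrix of covariates (an intercept is added).
#' @return A `neutro_logit`: tibble of terms (estimate, SE, OR, Wald 95% CI,
#'   p) plus `n_used`, `n_dropped`, `converged`, `separation`,
#'   `deviance_trace`.
#' @export
fit_logistic <- function(outcome, design) {
  design <- as.data.frame(design)
  y <- as.numeric(outcome)
  ok <- !is.na(y) & stats::complete.cases(design)
  y <- y[ok]
  x_df <- design[ok, , drop = FALSE]
  n <- length(y)
  if (!all(y %in% c(0, 1))) {
    stop("outcome must be binary (0/1 or logical)", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; association undefined", call. = FALSE)
  }
  x <- stats::model.matrix(~., data = x_df)

  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop(
      "design is rank deficient; collinear column(s): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }

  b <- numeric(ncol(x))
  dev <- function(b) {
    eta <- drop(x %*% b)
    # log1p(exp()) stable on both tails
    -2 * sum(y * eta - log1p(exp(pmin(eta, 700))))
  }
  dev_trace <- dev(b)
  converged <- FALSE
  for (iter in seq_len(100L)) {
    eta <- drop(x %*% b)
    p <- stats::plogis(eta)
    score <- drop(crossprod(x, y - p))
    if (max(abs(score)) < 1e-8) {
      converged <- TRUE
      break
    }
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(x, z, w)
    b_new <- fit$coefficients
    # step-halve if the deviance would increase (likelihood must not drop)
    step <- b_new - b
    d_old <- dev_trace[length(dev_trace)]
    for (h in 0:20) {
      d_new <- dev(b + step / 2^h)
      if (d_new <= d_old + 1e-12) break
    }
    b <- b + step / 2^h
    dev_trace <- c(dev_trace, d_new)
  }

  separation <- any(abs(b) > 15)
  if (separation) {
    warning(
      "possible (quasi-)separation: a coefficient exceeds 15 in absolute ",
      "value; odds ratios are unreliable",
      call. = FALSE
    )
  }

  p_fit <- stats::plogis(drop(x %*% b))
  w <- pmax(p_fit * (1 - p_fit), 1e-10)
  info <- crossprod(x * sqrt(w))
  se <- sqrt(diag(solve(info)))
  zval <- b / se
  terms <- tibble::tibble(
    term = colnames(x),
    estimate = unname(b),
    se = unname(se),
    or = exp(unname(b)),
    ci_lo = exp(unname(b - 1.96 * se)),
    ci_hi = exp(unname(b + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(unname(zval)))
  )
  structure(
    list(
      terms = terms, n_used = n, n_dropped = sum(!ok),
      converged = converged, separation = separation,
      deviance_trace = dev_trace
    ),
    class = "neutro_logit"
  )
}

#' @export
print.neutro_logit <- function(x, ...) {
  cat(sprintf(
    "<logistic fit> n = %d (%d dropped), %s%s\n",
    x$n_used, x$n_dropped,
    if (x$converged) "converged" else "NOT converged",
    if (x$separation) ", separation flagged" else ""
  ))
  print(dplyr::mutate(x$terms, dplyr::across(
    dplyr::where(is.numeric), ~ signif(.x, 4)
  )))
  invisible(x)
}

#' The fixed confounder adjustment set
#'
#' Chronic PA colonization, Charlson index, total leukocytes, percentage of
#' lymphocytes and of eosinophils, platelets, CRP, fibrinogen, total protein,
#' albumin and ESR — the clinically meaningful confounders of the registry
#' analysis. Percentages are derived from the cell counts when not present
#' as columns.
#'
#' @return Character vector of design column names, in order.
#' @export
default_confounders <- function() {
  c(
    "pa_colonization", "charlson", "leukocytes", "lymphocytes_pct",
    "eosinophils_pct", "platelets", "crp", "fibrinogen",
    "total_protein", "albumin", "esr"
  )
}

#' Confounder-adjusted association of the neutrophil clusters with severe
#' disease
#'
#' Fits `severe ~ above_threshold + confounders`, where `severe` is the
#' dichotomized score (FACED >= 5 or E-FACED >= 7 by default) and
#' `above_threshold` the cluster indicator. The exposure odds ratio is the
#' headline estimate; all covariate rows are returned for a forest-plot
#' display.
#'
#' @param cohort Scored cohort.
#' @param assignment A [dichotomize()] assignment.
#' @param scale `"FACED"` or `"EFACED"`.
#' @param cutoff Outcome cut-off; defaults to 5 (FACED) / 7 (EFACED).
#' @param confounders Confounder column names (default
#'   [default_confounders()]).
#' @return A `neutro_logit` with an extra `exposure` element naming the
#'   exposure term.
#' @export
adjusted_association <- function(cohort, assignment,
                                 scale = c("FACED", "EFACED"),
                                 cutoff = NULL,
                                 confounders = default_confounders()) {
  scale <- match.arg(scale)
  cutoff <- cutoff %||% switch(scale, FACED = 5L, EFACED = 7L)
  score_col <- switch(scale, FACED = "faced", EFACED = "efaced")
  if (!score_col %in% names(cohort)) {
    stop("cohort is not scored; run score_cohort() first", call. = FALSE)
  }
  data <- dplyr::left_join(cohort, assignment, by = "patient_id")
  data <- data[data$cluster %in% c("below", "above"), ]

  if (!"lymphocytes_pct" %in% names(data) &&
    all(c("lymphocytes", "leukocytes") %in% names(data))) {
    data$lymphocytes_pct <- 100 * data$lymphocytes / data$leukocytes
  }
  if (!"eosinophils_pct" %in% names(data) &&
    all(c("eosinophils", "leukocytes") %in% names(data))) {
    data$eosinophils_pct <- 100 * data$eosinophils / data$leukocytes
  }
  missing_cols <- setdiff(confounders, names(data))
  if (length(missing_cols) > 0) {
    stop(
      "confounders absent from cohort: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }

  outcome <- dichotomize_score(data[[score_col]], scale, cutoff)
  design <- data.frame(above_threshold = data$cluster == "above")
  for (v in confounders) design[[v]] <- as.numeric(data[[v]])

  fit <- fit_logistic(outcome, design)
  fit$exposure <- "above_thresholdTRUE"
  fit$scale <- scale
  fit$cutoff <- cutoff
  fit
}

#' Export a logistic fit table as CSV
#'
#' @param fit A `neutro_logit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_logistic <- function(fit, path) {
  readr::write_csv(fit$terms, path, na = "")
  invisible(path)
}
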