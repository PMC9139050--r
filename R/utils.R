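#' Percentage with half-up rounding
#'
#' Computes `100 * count / total` and rounds half-up to the requested number of
#' decimals, matching the reporting convention of clinical cohort tables
#' (e.g. 113 of 337 prints as 33.5). Base R's `round()` rounds half to even,
#' which a table formatter must not do.
#'
#' @param count Non-negative integer count, `count <= total`.
#' @param total Positive integer denominator.
#' @param decimals Number of decimals to keep (default 1).
#' @return The rounded percentage as a plain number.
#' @examples
#' percentage(113, 337, 1) # 33.5
#' percentage(337, 1034, 0) # 33
#' @export
percentage <- function(count, total, decimals = 1) {
  if (length(total) != 1L || !is.finite(total) || total <= 0) {
    stop("`total` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(count)) || any(count < 0) || any(count > total)) {
    stop("`count` must satisfy 0 <= count <= total", call. = FALSE)
  }
  round_half_up(100 * count / total, decimals)
}

#' Half-up rounding
#'
#' @param x Numeric vector.
#' @param digits Decimals to keep.
#' @return `x` rounded half-up.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small eps guards against 0.5 landing just below .5 in binary
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Significance stars for a p-value
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05, otherwise
#' the empty string. Boundaries are strict: p = 0.05 earns no star.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Character vector of star labels.
#' @examples
#' stars(c(0.0005, 0.03, 0.05))
#' @export
stars <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Two-sample test result container
#' @keywords internal
#' @noRd
new_test_result <- function(statistic, p_value, method, n_a, n_b, note = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(
    list(
      statistic = statistic, p_value = p_value, method = method,
      n_a = n_a, n_b = n_b, note = note
    ),
    class = "neutro_test"
  )
}

#' @export
print.neutro_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf(
    "  statistic = %.6g, p = %.4g (n_a = %d, n_b = %d)\n",
    x$statistic, x$p_value, x$n_a, x$n_b
  ))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

# md5 of an object via its canonical JSON serialization (no digest pkg needed)
hash_config <- function(x) {
  x <- strip_classes(x)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"),
    f
  )
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
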