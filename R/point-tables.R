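#' Severity-index point tables
#'
#' The scoring engine is table-driven: a point table lists, per component, the
#' record fields it reads and a banding rule awarding integer points. Three
#' band types cover the shipped indices:
#'
#' * `cut`: numeric field cut at `breaks`; `points` has one entry per band.
#'   `left_open[i]` controls whether the value must exceed (`TRUE`, `x > b`)
#'   or reach (`FALSE`, `x >= b`) break `i` to move past it, so mixed band
#'   closures such as "50-80% inclusive, above 80% exclusive" are expressible.
#' * `flag`: logical field; `points` awarded when `TRUE`.
#' * `ge_or_flag`: awarded when a numeric field reaches `ge` or a logical
#'   field is `TRUE` (the radiological-severity rule: three or more affected
#'   lobes, or cystic bronchiectasis).
#'
#' Shipped defaults implement the published FACED (0-7), E-FACED (0-9) and
#' BSI (0-26) indices. The source registry study does not print the point
#' values, so the defaults carry a provenance note and should be verified
#' against the original index publications before clinical use; any
#' correction is config-only.
#'
#' @param bsi_hospitalization_lookback `"prior_year"` (default; matches the
#'   registry variable "hospitalizations for exacerbations in the previous
#'   year") or `"two_years"` (the original index definition; requires a
#'   `hospitalizations_two_years` column).
#' @return A named list of `neutro_point_table` objects
#'   (`faced`, `efaced`, `bsi`).
#' @examples
#' tabs <- default_point_tables()
#' tabs$faced$max_total # 7
#' @export
default_point_tables <- function(
    bsi_hospitalization_lookback = c("prior_year", "two_years")) {
  bsi_hospitalization_lookback <- match.arg(bsi_hospitalization_lookback)
  hosp_field <- if (bsi_hospitalization_lookback == "prior_year") {
    "hospitalizations_prior_year"
  } else {
    "hospitalizations_two_years"
  }

  cut_comp <- function(name, field, breaks, points, left_open = FALSE) {
    list(
      name = name, type = "cut", field = field, breaks = breaks,
      points = points,
      left_open = rep_len(as.logical(left_open), length(breaks))
    )
  }
  flag_comp <- function(name, field, points) {
    list(name = name, type = "flag", field = field, points = points)
  }

  faced_comps <- list(
    cut_comp("fev1", "fev1_pct", 50, c(2L, 0L)),
    cut_comp("age", "age", 70, c(0L, 2L), left_open = TRUE),
    flag_comp("pa_colonization", "pa_colonization", 1L),
    cut_comp("extension", "radiological_lobes", 3, c(0L, 1L)),
    cut_comp("dyspnea", "dyspnea_mmrc", 3, c(0L, 1L))
  )
  efaced_comps <- c(
    list(cut_comp(
      "exacerbation", "hospitalizations_prior_year", 1, c(0L, 2L)
    )),
    faced_comps
  )
  bsi_comps <- list(
    cut_comp("age", "age", c(50, 70, 80), c(0L, 2L, 4L, 6L)),
    cut_comp("bmi", "bmi", 18.5, c(2L, 0L)),
    cut_comp("fev1", "fev1_pct", c(30, 50, 80), c(3L, 2L, 1L, 0L),
      left_open = c(FALSE, FALSE, TRUE)
    ),
    cut_comp("hospitalization", hosp_field, 1, c(0L, 5L)),
    cut_comp("exacerbations", "exacerbations_prior_year", 3, c(0L, 2L)),
    cut_comp("dyspnea", "dyspnea_mmrc", c(3, 4), c(0L, 2L, 3L)),
    flag_comp("pa_colonization", "pa_colonization", 3L),
    flag_comp("other_colonization", "other_colonization", 1L),
    list(
      name = "radiology", type = "ge_or_flag",
      field = "radiological_lobes", ge = 3,
      flag_field = "cystic_bronchiectasis", points = 1L
    )
  )

  note <- paste(
    "default point values transcribed from the original index publications;",
    "verify against those sources before clinical use"
  )
  list(
    faced = new_point_table("FACED", faced_comps, 7L, note),
    efaced = new_point_table("EFACED", efaced_comps, 9L, note),
    bsi = new_point_table("BSI", bsi_comps, 26L, note)
  )
}

new_point_table <- function(scale, components, max_total, provenance = "") {
  tab <- structure(
    list(
      scale = scale, components = components,
      max_total = as.integer(max_total), provenance = provenance
    ),
    class = "neutro_point_table"
  )
  validate_point_table(tab)
  tab
}

component_max <- function(comp) {
  switch(comp$type,
    cut = max(comp$points),
    flag = comp$points,
    ge_or_flag = comp$points,
    stop("unknown component type: ", comp$type, call. = FALSE)
  )
}

validate_point_table <- function(tab) {
  for (comp in tab$components) {
    pts <- comp$points
    if (any(pts < 0) || any(pts != floor(pts))) {
      stop(sprintf(
        "component `%s`: points must be non-negative integers", comp$name
      ), call. = FALSE)
    }
    if (comp$type == "cut") {
      if (is.unsorted(comp$breaks, strictly = TRUE)) {
        stop(sprintf(
          "component `%s`: breaks must be strictly increasing", comp$name
        ), call. = FALSE)
      }
      if (length(pts) != length(comp$breaks) + 1L) {
        stop(sprintf(
          "component `%s`: need one points entry per band", comp$name
        ), call. = FALSE)
      }
    }
  }
  total <- sum(vapply(tab$components, component_max, numeric(1)))
  if (total != tab$max_total) {
    stop(sprintf(
      "point table %s: per-component maxima sum to %d, declared max_total %d",
      tab$scale, total, tab$max_total
    ), call. = FALSE)
  }
  invisible(tab)
}

#' @export
print.neutro_point_table <- function(x, ...) {
  cat(sprintf(
    "<%s point table> max total %d, %d components\n",
    x$scale, x$max_total, length(x$components)
  ))
  for (comp in x$components) {
    cat(sprintf(
      "  %-18s %-10s max %d\n", comp$name, comp$type, component_max(comp)
    ))
  }
  invisible(x)
}

#' Serialize / load a point table as JSON
#'
#' @param table A `neutro_point_table`.
#' @param path JSON file path.
#' @return `read_point_table()` returns a validated `neutro_point_table`;
#'   `write_point_table()` returns `path` invisibly.
#' @export
write_point_table <- function(table, path) {
  jsonlite::write_json(
    unclass(table), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_point_table
#' @export
read_point_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- lapply(raw$components, function(comp) {
    comp$points <- as.integer(unlist(comp$points))
    if (!is.null(comp$breaks)) comp$breaks <- as.numeric(unlist(comp$breaks))
    if (!is.null(comp$left_open)) {
      comp$left_open <- as.logical(unlist(comp$left_open))
    }
    if (!is.null(comp$ge)) comp$ge <- as.numeric(comp$ge)
    comp
  })
  new_point_table(
    as.character(raw$scale), comps, as.integer(raw$max_total),
    as.character(raw$provenance %||% "")
  )
}
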