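#' Severity-category distribution per cluster
#'
#' Proportions of mild / moderate / severe patients in each neutrophil
#' cluster (complete-score patients only), with the omnibus chi-square across
#' the 2 x 3 table and significance stars.
#'
#' @param cohort Scored cohort.
#' @param assignment A [dichotomize()] assignment.
#' @param scale `"FACED"`, `"EFACED"` or `"BSI"`.
#' @return A `neutro_histogram`: tibble (cluster, category, n, proportion)
#'   with attributes `test` (a `neutro_test`) and `stars`.
#' @export
category_histogram <- function(cohort, assignment,
                               scale = c("FACED", "EFACED", "BSI")) {
  scale <- match.arg(scale)
  cat_col <- paste0(tolower(scale), "_cat")
  if (!cat_col %in% names(cohort)) {
    stop("cohort is not scored; run score_cohort() first", call. = FALSE)
  }
  data <- dplyr::left_join(cohort, assignment, by = "patient_id")
  data <- data[data$cluster %in% c("below", "above") &
    !is.na(data[[cat_col]]), ]
  if (!all(c("below", "above") %in% data$cluster)) {
    stop("a cluster is empty; category histogram undefined", call. = FALSE)
  }
  levels <- c("mild", "moderate", "severe")
  counts <- vapply(c("below", "above"), function(cl) {
    vapply(levels, function(l) {
      sum(data$cluster == cl & data[[cat_col]] == l)
    }, integer(1))
  }, integer(3))
  tab <- t(counts) # 2 x 3, rows below/above
  test <- tryCatch(
    suppressWarnings(chi_square(tab[, colSums(tab) > 0, drop = FALSE])),
    error = function(e) new_test_result(NA_real_, NA_real_, "chi-square",
      sum(tab[1, ]), sum(tab[2, ]),
      note = conditionMessage(e)
    )
  )
  out <- tibble::tibble(
    cluster = rep(c("below", "above"), each = 3),
    category = factor(rep(levels, 2), levels = levels, ordered = TRUE),
    n = unname(c(tab[1, ], tab[2, ])),
    proportion = unname(
      c(tab[1, ] / sum(tab[1, ]), tab[2, ] / sum(tab[2, ]))
    )
  )
  structure(
    out,
    scale = scale, test = test, stars = stars(test$p_value),
    class = c("neutro_histogram", class(tibble::tibble()))
  )
}

#' Pipeline configuration
#'
#' Exactly one of `input` (a cohort CSV path) or `generator` (a
#' [cohort_config()]) must be given.
#'
#' @param input Path to a cohort CSV, or `NULL`.
#' @param generator A [cohort_config()], or `NULL`.
#' @param output_dir Directory for the report bundle.
#' @param alpha Significance level (default 0.05).
#' @param grid_step Threshold grid spacing, cells/uL.
#' @param strategy Threshold selection strategy (see [select_threshold()]).
#' @param min_fraction Balance constraint for selection.
#' @param exclusions Exclusion re-analyses to run (logical flag columns).
#' @param outcome_cutoffs Named cut-offs for the severe-disease outcomes.
#' @param seed Seed for any generation step.
#' @return A validated `neutro_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = NULL,
                            output_dir = tempfile("neutroclust_"),
                            alpha = 0.05, grid_step = 10,
                            strategy = "most_balanced", min_fraction = 0.25,
                            exclusions = c("copd", "pa_colonization"),
                            outcome_cutoffs = c(FACED = 5L, EFACED = 7L),
                            seed = 1L) {
  if (is.null(input) == is.null(generator)) {
    stop("exactly one of `input` / `generator` must be provided",
      call. = FALSE
    )
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(
    list(
      input = input, generator = generator, output_dir = output_dir,
      alpha = alpha, grid_step = grid_step, strategy = strategy,
      min_fraction = min_fraction, exclusions = exclusions,
      outcome_cutoffs = outcome_cutoffs, seed = as.integer(seed)
    ),
    class = "neutro_pipeline_config"
  )
}

#' Run the full clustering pipeline
#'
#' Stages, in order: load or generate the cohort; compute severity scores;
#' sweep candidate thresholds; select the operating threshold; dichotomize;
#' build the comparison tables (overall plus each exclusion re-analysis);
#' category histograms; correlation matrices (all / above / below);
#' confounder-adjusted logistic associations for FACED and E-FACED. Every
#' artifact is written under `config$output_dir` and listed in a JSON
#' manifest carrying the configuration hash and seed, so a rerun with the
#' same config reproduces the bundle byte for byte. If no threshold is
#' eligible the pipeline halts after the scan stage and the manifest records
#' `"no_threshold_selected"` — no downstream tables are produced.
#'
#' @param config A [pipeline_config()].
#' @return A `neutro_bundle` list (cohort, scan, threshold, tables,
#'   histograms, correlations, fits, manifest), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "neutro_pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  manifest <- list(
    config = unclass(config)[c(
      "alpha", "grid_step", "strategy", "min_fraction", "exclusions",
      "outcome_cutoffs", "seed"
    )],
    config_hash = hash_config(unclass(config)),
    seed = config$seed,
    outputs = list(), warnings = list(), timing = list()
  )
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("pipeline stage `%s` failed: %s", name,
          conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        manifest$warnings[[length(manifest$warnings) + 1]] <<-
          list(stage = name, message = conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    manifest$timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  cohort <- stage("load", {
    if (!is.null(config$input)) {
      read_cohort(config$input)
    } else {
      gen <- config$generator
      if (!inherits(gen, "neutro_config")) gen <- do.call(cohort_config, gen)
      generate_cohort(gen)
    }
  })
  write_cohort(cohort, out("cohort.csv"))
  manifest$outputs$cohort <- "cohort.csv"

  scored <- stage("score", score_cohort(cohort))
  write_cohort(scored, out("scored.csv"))
  manifest$outputs$scored <- "scored.csv"

  scan <- stage("scan", scan_thresholds(
    scored,
    grid_step = config$grid_step, alpha = config$alpha
  ))
  readr::write_csv(scan$table, out("scan.csv"), na = "")
  manifest$outputs$scan <- "scan.csv"

  threshold <- stage("select", select_threshold(
    scan,
    strategy = config$strategy,
    alpha = config$alpha, min_fraction = config$min_fraction
  ))
  if (is.null(threshold)) {
    manifest$status <- "no_threshold_selected"
    manifest$threshold <- NULL
    jsonlite::write_json(manifest, out("manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    message(
      "no candidate threshold met the significance and balance criteria; ",
      "pipeline halted after the scan stage"
    )
    return(invisible(structure(
      list(
        cohort = scored, scan = scan, threshold = NULL,
        manifest = manifest, output_dir = config$output_dir
      ),
      class = "neutro_bundle"
    )))
  }
  manifest$threshold <- threshold
  scan$selected <- threshold
  scan$strategy <- config$strategy

  assignment <- stage("dichotomize", dichotomize(scored, threshold))
  pct_above <- percentage(sum(assignment$cluster == "above"),
    sum(assignment$cluster != "unassigned"),
    decimals = 1
  )
  manifest$cluster_sizes <- as.list(table(assignment$cluster))
  manifest$percent_above <- pct_above

  tables <- stage("compare", {
    excl <- c(list(none = NULL), stats::setNames(
      as.list(config$exclusions), config$exclusions
    ))
    lapply(excl, function(e) {
      comparison_table(scored, assignment, exclusion = e)
    })
  })
  for (nm in names(tables)) {
    f <- sprintf("comparison_%s.csv", nm)
    write_comparison(tables[[nm]], out(f))
    write_comparison(tables[[nm]], out(sub("csv$", "md", f)), "markdown")
    manifest$outputs[[paste0("comparison_", nm)]] <- f
  }

  histograms <- stage("histograms", {
    lapply(
      stats::setNames(nm = c("FACED", "EFACED", "BSI")),
      function(s) category_histogram(scored, assignment, s)
    )
  })
  for (nm in names(histograms)) {
    f <- sprintf("categories_%s.csv", tolower(nm))
    readr::write_csv(tibble::as_tibble(histograms[[nm]]), out(f), na = "")
    manifest$outputs[[paste0("categories_", tolower(nm))]] <- f
  }

  correlations <- stage("correlate", {
    lapply(
      stats::setNames(nm = c("all", "above", "below")),
      function(s) correlation_matrix(scored, assignment = assignment,
        subset = s)
    )
  })
  for (nm in names(correlations)) {
    f <- sprintf("correlation_%s.csv", nm)
    write_correlation(correlations[[nm]], out(f))
    manifest$outputs[[paste0("correlation_", nm)]] <- f
  }

  fits <- stage("associate", {
    lapply(
      stats::setNames(nm = names(config$outcome_cutoffs)),
      function(s) {
        adjusted_association(scored, assignment,
          scale = s,
          cutoff = config$outcome_cutoffs[[s]]
        )
      }
    )
  })
  for (nm in names(fits)) {
    f <- sprintf("association_%s.csv", tolower(nm))
    write_logistic(fits[[nm]], out(f))
    manifest$outputs[[paste0("association_", tolower(nm))]] <- f
    manifest$separation[[nm]] <- fits[[nm]]$separation
  }

  manifest$status <- "complete"
  jsonlite::write_json(manifest, out("manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(structure(
    list(
      cohort = scored, scan = scan, threshold = threshold,
      assignment = assignment, tables = tables, histograms = histograms,
      correlations = correlations, fits = fits, manifest = manifest,
      output_dir = config$output_dir
    ),
    class = "neutro_bundle"
  ))
}

#' @export
print.neutro_bundle <- function(x, ...) {
  cat("<neutroclust report bundle>\n")
  cat("  output_dir:", x$output_dir, "\n")
  if (is.null(x$threshold)) {
    cat("  status: no threshold selected (halted after scan)\n")
  } else {
    cat(sprintf("  selected threshold: %g cells/uL\n", x$threshold))
    sizes <- table(x$assignment$cluster)
    cat(sprintf(
      "  clusters: below %d / above %d\n", sizes[["below"]], sizes[["above"]]
    ))
  }
  invisible(x)
}
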