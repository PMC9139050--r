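tabs <- default_point_tables()

test_that("shipped tables reach the published maxima and validate", {
  expect_identical(tabs$faced$max_total, 7L)
  expect_identical(tabs$efaced$max_total, 9L)
  expect_identical(tabs$bsi$max_total, 26L)

  worst <- tibble::tibble(
    age = 85, bmi = 17, fev1_pct = 25, dyspnea_mmrc = 4L,
    radiological_lobes = 5L, exacerbations_prior_year = 4L,
    hospitalizations_prior_year = 2L, pa_colonization = TRUE,
    other_colonization = TRUE, cystic_bronchiectasis = TRUE
  )
  expect_identical(compute_scores(worst, tabs$faced)$total, 7L)
  expect_identical(compute_scores(worst, tabs$efaced)$total, 9L)
  expect_identical(compute_scores(worst, tabs$bsi)$total, 26L)

  best <- tibble::tibble(
    age = 40, bmi = 25, fev1_pct = 90, dyspnea_mmrc = 0L,
    radiological_lobes = 1L, exacerbations_prior_year = 0L,
    hospitalizations_prior_year = 0L, pa_colonization = FALSE,
    other_colonization = FALSE, cystic_bronchiectasis = FALSE
  )
  expect_identical(compute_scores(best, tabs$faced)$total, 0L)
  expect_identical(compute_scores(best, tabs$efaced)$total, 0L)
  expect_identical(compute_scores(best, tabs$bsi)$total, 0L)

  bad <- tabs$faced
  bad$max_total <- 6L
  expect_error(validate_point_table(bad), "max_total")
})

test_that("scorer agrees with the band-enumeration oracle on every combination", {
  grid <- expand.grid(
    age = c(45, 60, 75, 85), bmi = c(17, 25), fev1_pct = c(25, 40, 65, 90),
    hospitalizations_prior_year = c(0L, 1L),
    exacerbations_prior_year = c(1L, 4L),
    dyspnea_mmrc = c(1L, 3L, 4L),
    pa_colonization = c(FALSE, TRUE), other_colonization = c(FALSE, TRUE),
    radiological_lobes = c(2L, 4L), cystic_bronchiectasis = c(FALSE, TRUE)
  )
  faced <- compute_scores(grid, tabs$faced)$total
  efaced <- compute_scores(grid, tabs$efaced)$total
  bsi <- compute_scores(grid, tabs$bsi)$total
  expect_identical(faced, as.integer(with(
    grid,
    oracle_faced(fev1_pct, age, pa_colonization, radiological_lobes,
      dyspnea_mmrc)
  )))
  expect_identical(efaced, as.integer(with(
    grid,
    oracle_efaced(fev1_pct, age, pa_colonization, radiological_lobes,
      dyspnea_mmrc, hospitalizations_prior_year)
  )))
  expect_identical(bsi, as.integer(with(
    grid,
    oracle_bsi(age, bmi, fev1_pct, hospitalizations_prior_year,
      exacerbations_prior_year, dyspnea_mmrc, pa_colonization,
      other_colonization, radiological_lobes, cystic_bronchiectasis)
  )))
  # category agreement on the same sweep
  expect_identical(
    as.character(categorize(bsi, "BSI")),
    oracle_category(bsi, "BSI")
  )
})

test_that("boundary band values score exactly as published", {
  # FEV1 50 and 80 sit inside the 1-point BSI band; 70 years is FACED 0
  rec <- function(fev1, age) {
    tibble::tibble(
      age = age, bmi = 25, fev1_pct = fev1, dyspnea_mmrc = 0L,
      radiological_lobes = 1L, exacerbations_prior_year = 0L,
      hospitalizations_prior_year = 0L, pa_colonization = FALSE,
      other_colonization = FALSE, cystic_bronchiectasis = FALSE
    )
  }
  expect_identical(unname(compute_scores(rec(50, 40), tabs$bsi)$points[, "fev1"]), 1L)
  expect_identical(unname(compute_scores(rec(80, 40), tabs$bsi)$points[, "fev1"]), 1L)
  expect_identical(unname(compute_scores(rec(81, 40), tabs$bsi)$points[, "fev1"]), 0L)
  expect_identical(unname(compute_scores(rec(50, 40), tabs$faced)$points[, "fev1"]), 0L)
  expect_identical(
    unname(compute_scores(rec(49.9, 40), tabs$faced)$points[, "fev1"]), 2L
  )
  expect_identical(unname(compute_scores(rec(90, 70), tabs$faced)$points[, "age"]), 0L)
  expect_identical(
    unname(compute_scores(rec(90, 70.5), tabs$faced)$points[, "age"]), 2L
  )
})

test_that("missing inputs leave the total undefined, never imputed", {
  rec <- tiny_cohort()[2, ]
  rec$fev1_pct <- NA
  br <- score_breakdown(rec, tabs$faced)
  expect_identical(br$missing_components, "fev1")
  expect_true(is.na(br$total))
  # the other components still report their points
  expect_identical(unname(br$points["age"]), 2L)

  # out-of-range dyspnea grade is a validation error, not a silent 0
  bad <- tiny_cohort()[1, ]
  bad$dyspnea_mmrc <- 7L
  expect_error(compute_scores(bad, tabs$faced), "0..4")
})

test_that("worsening any single input never lowers a total (monotonicity)", {
  base <- tiny_cohort()[4, ]
  worsen <- list(
    age = 90, fev1_pct = 20, bmi = 15, dyspnea_mmrc = 4L,
    radiological_lobes = 6L, exacerbations_prior_year = 6L,
    hospitalizations_prior_year = 3L, pa_colonization = TRUE,
    other_colonization = TRUE, cystic_bronchiectasis = TRUE
  )
  for (tab in tabs) {
    t0 <- compute_scores(base, tab)$total
    for (v in names(worsen)) {
      rec <- base
      rec[[v]] <- worsen[[v]]
      expect_gte(compute_scores(rec, tab)$total, t0)
    }
  }
})

test_that("category binning and dichotomization follow the printed rules", {
  expect_identical(as.character(categorize(5, "FACED")), "severe")
  expect_identical(as.character(categorize(4, "EFACED")), "moderate")
  expect_identical(as.character(categorize(0, "BSI")), "mild")
  expect_error(categorize(8, "FACED"), "range")
  expect_error(categorize(2.5, "FACED"), "range")

  expect_true(dichotomize_score(5, "FACED", 5))
  expect_false(dichotomize_score(6, "EFACED", 7))
  expect_false(dichotomize_score(0, "FACED", 5))
  expect_error(dichotomize_score(3, "FACED", 8), "range")
})

test_that("point tables survive a JSON round-trip and drive the scorer", {
  path <- withr::local_tempfile(fileext = ".json")
  write_point_table(tabs$bsi, path)
  back <- read_point_table(path)
  grid <- tiny_cohort()
  expect_identical(
    compute_scores(grid, back)$total,
    compute_scores(grid, tabs$bsi)$total
  )

  # the two-year-lookback variant reads its own column
  tabs2 <- default_point_tables(bsi_hospitalization_lookback = "two_years")
  coh <- tiny_cohort()
  coh$hospitalizations_two_years <- c(0L, 0L, 1L, 0L, 0L, 0L)
  with1y <- compute_scores(coh, tabs$bsi)$total
  with2y <- compute_scores(coh, tabs2$bsi)$total
  expect_identical(with2y - with1y, c(0L, -5L, 0L, 0L, -5L, 0L))
})

test_that("score_cohort appends totals and categories consistently", {
  sc <- score_cohort(tiny_cohort())
  expect_true(all(c(
    "faced", "efaced", "bsi", "faced_cat", "efaced_cat", "bsi_cat"
  ) %in% names(sc)))
  expect_identical(
    as.character(sc$faced_cat), oracle_category(sc$faced, "FACED")
  )
  expect_true(all(sc$efaced >= sc$faced))
})
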