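scan_fixture <- function() {
  # a scan table built by hand to pin down the selection rules
  structure(
    list(
      table = tibble::tibble(
        threshold = c(4000, 5000, 6000),
        p_faced = c(0.01, 0.02, 0.001),
        p_efaced = c(0.04, 0.01, 0.002),
        n_above = c(60, 45, 30),
        n_below = c(40, 55, 70)
      ),
      alpha = 0.05, n_total = 100, selected = NULL, strategy = NULL
    ),
    class = "neutro_scan"
  )
}

test_that("scan records group sizes and exact p on tiny cohorts", {
  coh <- tibble::tibble(
    patient_id = sprintf("x%d", 1:4),
    neutrophils = c(1000, 2000, 8000, 9000),
    faced = c(2L, 2L, 9L, 9L), efaced = c(2L, 2L, 9L, 9L)
  )
  scan <- scan_thresholds(coh, grid = 5000)
  expect_identical(scan$table$n_above, 2L)
  expect_identical(scan$table$n_below, 2L)
  # a 2-vs-2 comparison cannot reach significance whatever the separation
  expect_gt(scan$table$p_faced, 0.05)

  # grid beyond the observed range: degenerate splits, p undefined
  far <- scan_thresholds(coh, grid = c(10000, 20000))
  expect_identical(far$table$n_above, c(0L, 0L))
  expect_true(all(is.na(far$table$p_faced)))

  expect_error(scan_thresholds(coh, grid = numeric(0)), "empty")
  expect_error(
    scan_thresholds(tibble::tibble(faced = 1, efaced = 1)),
    "neutrophils"
  )
})

test_that("n_above is non-increasing and complements n_below along the grid", {
  coh <- score_cohort(generate_cohort(cohort_config(300, seed = 9)))
  scan <- scan_thresholds(coh, grid_step = 100)
  expect_true(all(diff(scan$table$n_above) <= 0))
  expect_true(all(scan$table$n_above + scan$table$n_below == scan$n_total))
})

test_that("selection strategies follow their definitions", {
  scan <- scan_fixture()
  expect_equal(select_threshold(scan, "most_balanced"), 5000)
  expect_equal(select_threshold(scan, "highest_significant"), 6000)
  expect_equal(select_threshold(scan, "min_p"), 6000)
  expect_error(select_threshold(scan, "lowest_p"), "unknown")

  # balance constraint can empty the eligible set
  expect_null(select_threshold(scan, min_fraction = 0.8))

  # singleton eligibility: every strategy returns the same candidate
  scan1 <- scan_fixture()
  scan1$table$p_efaced <- c(0.5, 0.01, 0.5)
  for (s in c("most_balanced", "highest_significant", "min_p")) {
    expect_equal(select_threshold(scan1, s), 5000)
  }

  # balance ties break to the higher threshold
  scan2 <- scan_fixture()
  scan2$table$n_above <- c(45, 45, 30)
  scan2$table$n_below <- c(55, 55, 70)
  expect_equal(select_threshold(scan2, "most_balanced"), 5000)
})

test_that("selection is invariant to grid order and duplicates", {
  scan <- scan_fixture()
  shuffled <- scan
  shuffled$table <- scan$table[c(3, 1, 2), ]
  duplicated <- scan
  duplicated$table <- scan$table[c(1, 1, 2, 3, 3), ]
  for (s in c("most_balanced", "highest_significant", "min_p")) {
    expect_equal(select_threshold(shuffled, s), select_threshold(scan, s))
    expect_equal(select_threshold(duplicated, s), select_threshold(scan, s))
  }
})

test_that("cluster assignment is inclusive at the boundary", {
  coh <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    neutrophils = c(4990, 4989.9, NA)
  )
  asg <- dichotomize(coh, 4990)
  expect_identical(
    as.character(asg$cluster), c("above", "below", "unassigned")
  )
  expect_error(dichotomize(coh, -10))
})

test_that("a planted change-point is recovered by the minimum-p rule", {
  # scaled-down recovery check (full version in the acceptance suite)
  hits <- vapply(1:10, function(s) {
    coh <- score_cohort(generate_cohort(cohort_config(
      1034,
      seed = 300 + s,
      planted_threshold = 5000, effect_sizes = strong_effects()
    )))
    sel <- select_threshold(
      scan_thresholds(coh, grid_step = 20), "min_p"
    )
    !is.null(sel) && abs(sel - 5000) <= 200
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("recovery rate grows with the planted effect size", {
  rate_at <- function(mult) {
    eff <- list(
      fev1_pct = -10 * mult, age = 3 * mult,
      hospitalizations_prior_year = 0.4 * mult
    )
    hits <- vapply(1:12, function(s) {
      coh <- score_cohort(generate_cohort(cohort_config(
        600,
        seed = 500 + s, planted_threshold = 5000, effect_sizes = eff
      )))
      sel <- select_threshold(
        scan_thresholds(coh, grid_step = 50), "min_p",
        min_fraction = 0.1
      )
      !is.null(sel) && abs(sel - 5000) <= 500
    }, logical(1))
    mean(hits)
  }
  rates <- vapply(c(0.25, 1, 3), rate_at, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("the null model mostly selects nothing", {
  none <- vapply(1:20, function(s) {
    coh <- score_cohort(generate_cohort(
      cohort_config(500, seed = 800 + s, planted_threshold = NULL)
    ))
    is.null(select_threshold(scan_thresholds(coh, grid_step = 100)))
  }, logical(1))
  expect_gte(mean(none), 0.7) # scaled-down demonstration of selection bias
})
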