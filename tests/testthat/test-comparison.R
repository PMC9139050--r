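test_that("pooled t matches the textbook formula and stats::t.test", {
  res <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # hand-computable case: pooled sd 0.577, |t| ~ 24.5 on 6 df
  res2 <- student_t(c(0, 0, 1, 1), c(10, 10, 11, 11))
  expect_lt(res2$p_value, 0.001)
  expect_equal(res2$statistic, -10 / sqrt((1 / 3) * (1 / 4 + 1 / 4)),
    tolerance = 1e-12
  )

  set.seed(12)
  for (rep in 1:25) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    ours <- student_t(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    welch <- student_t(a, b, pooled = FALSE)
    ref_w <- stats::t.test(a, b)
    expect_equal(welch$p_value, ref_w$p.value, tolerance = 1e-10)
  }

  # degenerate conventions: zero pooled variance
  expect_equal(student_t(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_equal(student_t(c(2, 2, 2), c(3, 3))$p_value, 0)
  expect_error(student_t(1, c(1, 2)), ">= 2")
})

test_that("chi-square matches hand computation and stats::chisq.test", {
  res <- chi_square(rbind(c(50, 50), c(50, 50)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # all expected counts 50: statistic = 4 * 40^2 / 50 = 128
  res2 <- chi_square(rbind(c(90, 10), c(10, 90)))
  expect_equal(res2$statistic, 128)
  expect_lt(res2$p_value, 0.001)

  u <- rbind(c(10, 10, 10), c(10, 10, 10))
  expect_match(chi_square(u)$method, "df = 2")

  set.seed(3)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    tab <- matrix(rpois(2 * k, 30) + 5, nrow = 2)
    ours <- chi_square(tab)
    ref <- stats::chisq.test(tab, correct = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  yates <- chi_square(rbind(c(12, 8), c(5, 15)), correct = TRUE)
  ref_y <- stats::chisq.test(rbind(c(12, 8), c(5, 15)), correct = TRUE)
  expect_equal(yates$statistic, unname(ref_y$statistic), tolerance = 1e-10)

  expect_error(chi_square(rbind(c(0, 0), c(5, 5))), "margin")
  expect_warning(chi_square(rbind(c(2, 30), c(3, 28))), "expected")
})

test_that("stars follow the strict footnote boundaries", {
  expect_identical(
    stars(c(0.0005, 0.005, 0.03, 0.05, 0.2, 0.001, 0.01)),
    c("***", "**", "*", "", "", "**", "*")
  )
  expect_error(stars(1.2), "\\[0, 1\\]")
})

test_that("percent cells recompute from count and group size", {
  expect_equal(percentage(113, 337, 1), 33.5)
  expect_equal(percentage(337, 1034, 0), 33)
  expect_equal(percentage(0, 50, 1), 0)
  expect_error(percentage(3, 0), "positive")
  expect_error(percentage(5, 4), "count")
})

test_that("comparison tables summarize, test and star each variable", {
  coh <- score_cohort(generate_cohort(cohort_config(800, seed = 21)))
  asg <- dichotomize(coh, 4990)
  tab <- comparison_table(coh, asg)

  neut <- tab[tab$variable == "neutrophils", ]
  expect_identical(neut$stars, "***")
  below_vals <- coh$neutrophils[coh$neutrophils < 4990]
  expect_equal(neut$below_mean, mean(below_vals), tolerance = 1e-12)

  pa <- tab[tab$variable == "pa_colonization", ]
  expect_equal(
    pa$below_pct, percentage(pa$below_count, pa$n_below, 1)
  )

  smoking <- tab[tab$variable == "smoking_status", ]
  expect_identical(nrow(smoking), 3L)
  expect_length(unique(smoking$p), 1L) # one omnibus test per block

  expect_error(
    comparison_table(coh, asg, specs = variable_spec("height", "continuous")),
    "height"
  )
})

test_that("exclusion shrinks groups by exactly the per-group flag counts", {
  coh <- score_cohort(generate_cohort(cohort_config(600, seed = 33)))
  asg <- dichotomize(coh, 4990)
  full <- comparison_table(coh, asg)
  excl <- comparison_table(coh, asg, exclusion = "copd")

  flags <- table(asg$cluster[coh$copd], useNA = "no")
  expect_identical(
    attr(full, "group_sizes") - attr(excl, "group_sizes"),
    c(below = unname(flags["below"]), above = unname(flags["above"]))
  )
  expect_identical(attr(excl, "exclusion"), "copd")

  # planted differences keep their direction when an independent flag is
  # excluded (copd is generated independently of the blood analytes)
  for (v in c("fibrinogen", "crp", "fev1_pct")) {
    d_full <- full$above_mean[full$variable == v] -
      full$below_mean[full$variable == v]
    d_excl <- excl$above_mean[excl$variable == v] -
      excl$below_mean[excl$variable == v]
    expect_identical(sign(d_full), sign(d_excl))
  }
})

test_that("a +1.5 SD planted shift at n = 1000/group earns three stars", {
  set.seed(64)
  coh <- tibble::tibble(
    patient_id = as.character(1:2000),
    neutrophils = rep(c(3000, 6000), each = 1000),
    biomarker = rnorm(2000, mean = rep(c(0, 1.5), each = 1000))
  )
  tab <- comparison_table(
    coh, dichotomize(coh, 4990),
    specs = variable_spec("biomarker", "continuous")
  )
  expect_identical(tab$stars, "***")
})

test_that("formatted tables use printed-style cells and full-precision CSV", {
  coh <- score_cohort(tiny_cohort())
  asg <- dichotomize(coh, 4990)
  tab <- suppressWarnings(comparison_table(coh, asg))
  f <- format_comparison(tab)
  expect_match(f$below[f$variable == "age"], "^\\d+\\.\\d \\(\\d+\\.\\d\\)$")

  csv <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".md")
  write_comparison(tab, csv)
  write_comparison(tab, md, format = "markdown")
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tab))
  expect_match(readLines(md)[1], "^\\| variable")
})
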