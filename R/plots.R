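#' Plot the p-value-versus-threshold sweep
#'
#' Log-scaled p-value curves for FACED and E-FACED across the candidate
#' grid, with a horizontal line at the significance level and, when
#' available, a vertical line at the selected threshold.
#'
#' @param scan A `neutro_scan`.
#' @return A ggplot object.
#' @export
plot_threshold_scan <- function(scan) {
  long <- tidyr::pivot_longer(scan$table, c("p_faced", "p_efaced"),
    names_to = "score", values_to = "p"
  )
  long$score <- ifelse(long$score == "p_faced", "FACED", "EFACED")
  gg <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$threshold, y = .data$p, colour = .data$score)
  ) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = scan$alpha,
      colour = "red", linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "neutrophil threshold (cells/uL)",
      y = "Mann-Whitney p (log scale)", colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(scan$selected)) {
    gg <- gg + ggplot2::geom_vline(
      xintercept = scan$selected,
      linetype = "dashed", colour = "goldenrod"
    )
  }
  gg
}

#' Plot the per-cluster severity-category histogram
#'
#' @param histogram A [category_histogram()] result.
#' @return A ggplot object.
#' @export
plot_category_histogram <- function(histogram) {
  ggplot2::ggplot(
    tibble::as_tibble(histogram),
    ggplot2::aes(x = .data$category, y = .data$proportion,
      fill = .data$cluster)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      title = paste0(
        attr(histogram, "scale"), " categories ", attr(histogram, "stars")
      ),
      x = NULL, y = "proportion of cluster", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Dot-matrix correlation plot
#'
#' Dot size and colour encode r (blue positive, red negative); entries with
#' p > 0.05 are crossed out.
#'
#' @param cormat A `neutro_cormat`.
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(cormat) {
  idx <- which(upper.tri(cormat$r, diag = FALSE), arr.ind = TRUE)
  df <- tibble::tibble(
    var_a = factor(cormat$variables[idx[, 1]], levels = cormat$variables),
    var_b = factor(cormat$variables[idx[, 2]], levels = cormat$variables),
    r = cormat$r[idx],
    masked = cormat$masked[idx]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var_b, y = .data$var_a)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$r),
      colour = .data$r)) +
    ggplot2::geom_point(
      data = df[df$masked, ],
      shape = 4, size = 3, colour = "grey30"
    ) +
    ggplot2::scale_colour_gradient2(
      low = "red", mid = "white", high = "blue", limits = c(-1, 1)
    ) +
    ggplot2::scale_size_area(max_size = 6, guide = "none") +
    ggplot2::labs(
      x = NULL, y = NULL, colour = "r",
      title = paste0("pairwise correlations (", cormat$subset, ")")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Forest plot of an adjusted logistic fit
#'
#' Odds ratios with Wald 95% intervals per term, reference line at 1,
#' exposure term highlighted.
#'
#' @param fit A `neutro_logit` (e.g. from [adjusted_association()]).
#' @return A ggplot object.
#' @export
plot_forest <- function(fit) {
  df <- fit$terms[fit$terms$term != "(Intercept)", ]
  df$headline <- df$term == (fit$exposure %||% "")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$or, y = stats::reorder(.data$term, .data$or)
  )) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$headline), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = "grey50"), guide = "none"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
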