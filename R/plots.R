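#' Plot a fitted standard curve
#'
#' Dilution points with the fitted regression line; the subtitle reports
#' slope, efficiency and R-squared.
#'
#' @param object A [fit_standard_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot(object$points, aes(x = .data$log10_copies, y = .data$ct)) +
    geom_point(size = 2) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "steelblue") +
    labs(
      title = paste("Standard curve", object$assay_id %||% ""),
      subtitle = sprintf("slope %.3f, E = %.3f, R² = %.4f%s",
                         object$slope, object$efficiency, object$r_squared,
                         if (object$usable) "" else " (below usability threshold)"),
      x = "log10 input copies", y = "Ct"
    ) +
    theme_minimal()
}

#' Plot a DNA-content peak with its gate
#'
#' Kernel-density estimate of the intensity distribution, with the
#' detected G0/G1 mode and the analysis gate marked.
#'
#' @param object A [detect_g0g1_peak()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peak_stats <- function(object, ...) {
  df <- tibble(intensity = object$data)
  ggplot(df, aes(x = .data$intensity)) +
    geom_density(fill = "grey85", colour = "grey40") +
    geom_vline(xintercept = object$mode, colour = "firebrick") +
    geom_vline(xintercept = object$gate, linetype = "dashed",
               colour = "steelblue") +
    labs(
      title = "G0/G1 peak",
      subtitle = sprintf("mode %.3g, CV %.2f%%, skew %.3f, %d gated events",
                         object$mode, object$cv_percent, object$skew,
                         object$n_events),
      x = object$channel, y = "density"
    ) +
    theme_minimal()
}

#' Scatter of single-unit relative copy numbers by cohort
#'
#' One point per unit, jittered within group/region strata, with the
#' cohort mean and its 95% confidence interval overlaid — the standard
#' way single-nucleus copy-number cohorts are displayed.
#'
#' @param calls A [call_copy_number()] (or [rcn_table()]) output carrying
#'   `rcn`, `group` and `region`.
#' @param bounds Optional [build_bounds_table()]; when supplied, modeled
#'   per-copy-number intervals are drawn as horizontal bands.
#' @return A ggplot object.
#' @export
plot_cohort_rcn <- function(calls, bounds = NULL) {
  check_columns(calls, c("rcn", "group", "region"), "calls")
  calls <- dplyr::mutate(calls,
                         cohort = paste(.data$group, .data$region, sep = " "))
  p <- ggplot(calls, aes(x = .data$cohort, y = .data$rcn))
  if (!is.null(bounds)) {
    p <- p + geom_rect(
      data = as_tibble(bounds),
      aes(ymin = .data$lower, ymax = .data$upper),
      xmin = -Inf, xmax = Inf, fill = "grey90", inherit.aes = FALSE
    )
  }
  p +
    geom_jitter(width = 0.15, height = 0, shape = 18, alpha = 0.7) +
    stat_summary(fun = mean, geom = "point", colour = "red", size = 3) +
    stat_summary(fun.data = function(v) {
      m <- mean(v)
      half <- qt(0.975, df = length(v) - 1) * sd(v) / sqrt(length(v))
      data.frame(y = m, ymin = m - half, ymax = m + half)
    }, geom = "errorbar", colour = "red", width = 0.2) +
    labs(x = NULL, y = "relative copy number") +
    theme_minimal()
}

#' Bar chart of copy-number bin histograms per cohort
#'
#' @param calls A [call_copy_number()] output with `bin`, `group`,
#'   `region` columns.
#' @return A ggplot object.
#' @export
plot_bin_histogram <- function(calls) {
  check_columns(calls, c("bin", "group", "region"), "calls")
  calls <- dplyr::mutate(
    calls,
    bin = factor(.data$bin, levels = c(as.character(1:6), ">6")),
    cohort = paste(.data$group, .data$region, sep = " ")
  )
  ggplot(calls, aes(x = .data$bin)) +
    geom_bar(fill = "steelblue") +
    facet_wrap(~cohort) +
    labs(x = "copy-number bin", y = "nuclei") +
    theme_minimal()
}

#' Per-group positive fractions from PNA quantification
#'
#' @param fractions A [positive_fraction()] output.
#' @return A ggplot object.
#' @export
plot_positive_fraction <- function(fractions) {
  check_columns(fractions, c("group", "fraction"), "fractions")
  ggplot(fractions, aes(x = .data$group, y = 100 * .data$fraction)) +
    geom_col(fill = "darkgreen", width = 0.6) +
    labs(x = NULL, y = "% nuclei above detection threshold") +
    theme_minimal()
}
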