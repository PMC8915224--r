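# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @exportS3Method generics::tidy
tidy.cohort_fit <- function(x, conf.level = 0.95, ...) {
  ci <- suppressMessages(confint(x$fit, level = conf.level))
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = ci[, 1],
    conf.high = ci[, 2]
  )
}

#' @exportS3Method generics::glance
glance.cohort_fit <- function(x, ...) {
  tibble(
    r = x$r, r.squared = x$r2, p.value = x$p,
    transform = x$transform, nobs = x$n
  )
}

#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  x$pairwise
}

#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p, nobs = x$n)
}

#' @exportS3Method generics::tidy
tidy.diagnostic_performance <- function(x, ...) {
  tibble(
    condition = x$condition,
    metric = c("sensitivity", "specificity"),
    estimate = c(x$sensitivity, x$specificity),
    conf.low = c(x$sens_ci[1], x$spec_ci[1]),
    conf.high = c(x$sens_ci[2], x$spec_ci[2]),
    band = band_label(c(x$sensitivity, x$specificity))
  )
}

#' @exportS3Method generics::glance
glance.diagnostic_performance <- function(x, ...) {
  tibble(
    condition = x$condition, tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
    sensitivity = x$sensitivity, specificity = x$specificity,
    nobs = x$tp + x$fp + x$fn + x$tn
  )
}

#' @exportS3Method generics::tidy
tidy.cutoff_set <- function(x, ...) {
  tibble(
    scale = c("nbfv", "ffr", "pbf"),
    overweight = c(x$nbfv_overweight, x$ffr_overweight, x$pbf_overweight),
    obese = c(x$nbfv_obese, x$ffr_obese, x$pbf_obese)
  )
}

#' Plot an HU histogram with detected tissue peaks
#'
#' @param object an `hu_histogram` from [build_histogram()].
#' @param peaks optionally, the matching [find_tissue_peaks()] result; the
#'   fat/lean peaks and the midpoint threshold are drawn when supplied.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hu_histogram <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_value, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::labs(x = "attenuation (HU)", y = "voxels") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p +
      ggplot2::geom_vline(
        xintercept = c(peaks$fat_peak_hu, peaks$lean_peak_hu),
        linetype = "dashed", colour = "steelblue"
      ) +
      ggplot2::geom_vline(
        xintercept = peaks$midpoint_hu,
        colour = "firebrick"
      )
  }
  p
}

#' Plot a cohort regression fit
#'
#' Scatter of the (possibly log-transformed) data with the fitted line.
#'
#' @param object a `cohort_fit` from [correlate()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_fit <- function(object, ...) {
  lab <- if (object$transform == "ln_ln") {
    c(paste0("ln(", object$x_name, ")"), paste0("ln(", object$y_name, ")"))
  } else {
    c(object$x_name, object$y_name)
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope,
      colour = "firebrick"
    ) +
    ggplot2::labs(
      x = lab[1], y = lab[2],
      subtitle = sprintf("r = %.3f, r² = %.3f, n = %d", object$r, object$r2, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Boxplot of a value across fat-category groups
#'
#' @param object a `group_comparison` from [compare_fc_groups()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.group_comparison <- function(object, ...) {
  df <- mutate(object$data,
    group = factor(.data$group, levels = intersect(fc_levels(), unique(.data$group)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(
      x = "fat category", y = "value",
      subtitle = sprintf(
        "Kruskal-Wallis H = %.2f, p = %.3g", object$statistic, object$p
      )
    ) +
    ggplot2::theme_minimal()
}
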