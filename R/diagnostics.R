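#' Confusion counts for FFR-based detection of obesity or overweight
#'
#' For the obesity condition, disease-positive means a visual fat category
#' of obese and test-positive means an FFR class of obese (FFR at or above
#' the obesity cutoff). For the overweight condition, disease-positive
#' means a visual category of overweight and test-positive an FFR class of
#' overweight (FFR in the half-open band between the two cutoffs); all
#' other categories count as disease-negative.
#'
#' @param data a data frame with a visual fat category column and an FFR
#'   class column (as from [classify_by_ffr()]).
#' @param condition `"obesity"` or `"overweight"`.
#' @param visual_fc,ffr_class tidy-eval columns.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`,
#'   and the condition.
#' @export
confusion_table <- function(data, condition = c("obesity", "overweight"),
                            visual_fc = visual_fc, ffr_class = ffr_class) {
  condition <- match.arg(condition)
  fc <- as.character(dplyr::pull(data, {{ visual_fc }}))
  cls <- as.character(dplyr::pull(data, {{ ffr_class }}))
  if (anyNA(fc) || anyNA(cls)) {
    abort("every record needs both a visual fat category and an FFR class.")
  }
  bad <- setdiff(unique(fc), fc_levels())
  if (length(bad)) {
    abort(sprintf("unknown visual fat category: %s", paste(bad, collapse = ", ")))
  }
  target <- if (condition == "obesity") "obese" else "overweight"
  disease <- fc == target
  test <- cls == target
  structure(
    list(
      tp = sum(disease & test), fp = sum(!disease & test),
      fn = sum(disease & !test), tn = sum(!disease & !test),
      condition = condition
    ),
    class = "confusion_counts"
  )
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided exact interval for a binomial proportion, obtained by
#' inverting the binomial tail tests. The lower bound is 0 when there are
#' no successes and the upper bound 1 when all trials succeed.
#'
#' @param k successes.
#' @param n trials.
#' @param level confidence level.
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
exact_binomial_ci <- function(k, n, level = 0.95) {
  if (n <= 0 || k < 0 || k > n) abort("need 0 <= k <= n with n > 0.")
  as.numeric(binom.test(k, n, conf.level = level)$conf.int)
}

#' Sensitivity and specificity with exact binomial CIs
#'
#' Point estimates are `tp / (tp + fn)` and `tn / (tn + fp)`; intervals are
#' two-sided Clopper-Pearson at the requested level. Estimates and bounds
#' are reported to 2 decimals (half-away-from-zero); full precision is kept
#' in the returned object.
#'
#' @param counts a `confusion_counts` from [confusion_table()].
#' @param level confidence level.
#' @return A list of class `diagnostic_performance`.
#' @export
sens_spec_with_ci <- function(counts, level = 0.95) {
  if (counts$tp + counts$fn == 0) abort("no disease-positive animals: sensitivity undefined.")
  if (counts$tn + counts$fp == 0) abort("no disease-negative animals: specificity undefined.")
  sens <- counts$tp / (counts$tp + counts$fn)
  spec <- counts$tn / (counts$tn + counts$fp)
  structure(
    list(
      condition = counts$condition,
      tp = counts$tp, fp = counts$fp, fn = counts$fn, tn = counts$tn,
      sensitivity = sens, specificity = spec,
      sens_ci = exact_binomial_ci(counts$tp, counts$tp + counts$fn, level),
      spec_ci = exact_binomial_ci(counts$tn, counts$tn + counts$fp, level),
      level = level
    ),
    class = "diagnostic_performance"
  )
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<diagnostic_performance> %s (tp %d, fp %d, fn %d, tn %d)\n",
      "  sensitivity %.2f (%d%% CI: %.2f-%.2f) [%s]\n",
      "  specificity %.2f (%d%% CI: %.2f-%.2f) [%s]\n"
    ),
    x$condition, x$tp, x$fp, x$fn, x$tn,
    round_report(x$sensitivity, 2), round(100 * x$level),
    round_report(x$sens_ci[1], 2), round_report(x$sens_ci[2], 2),
    band_label(x$sensitivity),
    round_report(x$specificity, 2), round(100 * x$level),
    round_report(x$spec_ci[1], 2), round_report(x$spec_ci[2], 2),
    band_label(x$specificity)
  ))
  invisible(x)
}

#' Qualitative band for a sensitivity or specificity value
#'
#' Values below 0.5 are low, 0.5-0.69 moderate, 0.7-0.89 high, and 0.9-1
#' very high; band edges are closed on the left.
#'
#' @param value proportion in `[0, 1]` (vectorized).
#' @return Character vector of band labels.
#' @export
band_label <- function(value) {
  if (any(value < 0 | value > 1, na.rm = TRUE)) {
    abort("`value` must lie in [0, 1].")
  }
  as.character(cut(value,
    breaks = c(-Inf, 0.5, 0.7, 0.9, Inf),
    labels = c("low", "moderate", "high", "very_high"),
    right = FALSE
  ))
}

#' Example validation cohort of 54 cats
#'
#' A reconstructed 54-cat postmortem cohort for illustrating FFR-based
#' classification and diagnostic-performance computation: 14 obese, 20
#' overweight, 11 normal-weight, and 9 underweight animals by visual
#' assessment, of which six disagree with their FFR class (two visually
#' overweight cats with FFR 4.8 and 3.8, one visually obese cat with FFR
#' 3.3, two visually normal cats with FFR 1.8 and 1.6, and one visually
#' overweight cat with FFR 1.1). All remaining animals carry a
#' representative FFR inside the band their visual category implies under
#' the reference cutoffs 1.6 / 3.5.
#'
#' @return Tibble with `cat_id`, `visual_fc`, and `ffr`.
#' @export
example_cohort <- function() {
  rows <- dplyr::bind_rows(
    tibble(visual_fc = "obese", ffr = c(rep(5.0, 13), 3.3)),
    tibble(visual_fc = "overweight", ffr = c(rep(2.5, 17), 4.8, 3.8, 1.1)),
    tibble(visual_fc = "normal", ffr = c(rep(1.0, 9), 1.8, 1.6)),
    tibble(visual_fc = "underweight", ffr = rep(0.5, 9))
  )
  mutate(rows, cat_id = sprintf("cat%02d", dplyr::row_number()), .before = 1)
}
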