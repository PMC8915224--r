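#' Correlation / simple regression with automatic natural-log fallback
#'
#' Fits an ordinary least-squares regression of `y` on `x` and reports the
#' Pearson correlation, r-squared, and the two-sided p value of the slope.
#' With `transform = "auto"` the fit is first attempted untransformed; if a
#' Shapiro-Wilk test of the residuals rejects normality at `alpha`, both
#' variables are natural-log transformed (requires positive values) and the
#' fit repeated, recording the transform used. `"ln"` forces the log-log
#' fit; `"none"` forbids it.
#'
#' @param data a data frame.
#' @param x,y tidy-eval columns.
#' @param transform `"auto"`, `"none"`, or `"ln"`.
#' @param alpha significance level for the residual normality check.
#' @return An object of class `cohort_fit` wrapping the `lm` fit, with
#'   [tidy()] and [glance()] methods.
#' @export
correlate <- function(data, x, y, transform = c("auto", "none", "ln"),
                      alpha = 0.05) {
  transform <- match.arg(transform)
  x_name <- rlang::as_label(rlang::enquo(x))
  y_name <- rlang::as_label(rlang::enquo(y))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 3) abort("need at least 3 paired non-missing values.")

  fit_scale <- function(xs, ys, label) {
    fit <- lm(ys ~ xs)
    structure(
      list(
        fit = fit,
        intercept = unname(coef(fit)[1]),
        slope = unname(coef(fit)[2]),
        r = cor(xs, ys),
        r2 = cor(xs, ys)^2,
        p = suppressWarnings(summary(fit)$coefficients[2, 4]),
        transform = label,
        n = length(xs),
        x_name = x_name,
        y_name = y_name,
        data = tibble(x = xs, y = ys)
      ),
      class = "cohort_fit"
    )
  }

  take_ln <- function() {
    if (any(xv <= 0) || any(yv <= 0)) {
      abort("natural-log transform requires positive values.",
        class = "felifat_error_nonpositive_ln"
      )
    }
    fit_scale(log(xv), log(yv), "ln_ln")
  }

  if (transform == "ln") {
    return(take_ln())
  }
  plain <- fit_scale(xv, yv, "none")
  if (transform == "none") {
    return(plain)
  }
  res <- stats::residuals(plain$fit)
  normal_ok <- length(unique(round(res, 12))) < 3 ||
    shapiro.test(res)$p.value >= alpha
  if (normal_ok) plain else take_ln()
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf(
    "<cohort_fit> %s ~ %s (transform %s, n = %d)\n  intercept %.4g, slope %.4g, r = %.3f, r2 = %.3f, p = %.3g\n",
    x$y_name, x$x_name, x$transform, x$n,
    x$intercept, x$slope, x$r, x$r2, x$p
  ))
  invisible(x)
}

#' Drop animals by muscle grade
#'
#' Removes rows whose muscle grade is in `exclude` (atrophy inflates and
#' hypertrophy deflates the lean compartment, degrading %BF-based
#' comparisons). The number of removed rows is reported and attached as the
#' `n_removed` attribute.
#'
#' @param data a data frame with a muscle grade column.
#' @param exclude grades to drop.
#' @param muscle_grade tidy-eval column.
#' @return Filtered tibble with attribute `n_removed`.
#' @export
filter_by_muscle <- function(data, exclude = c("atrophic", "hypertrophic"),
                             muscle_grade = muscle_grade) {
  grades <- dplyr::pull(data, {{ muscle_grade }})
  keep <- !grades %in% exclude
  out <- as_tibble(data)[keep, , drop = FALSE]
  inform(sprintf("filter_by_muscle: removed %d of %d rows.", sum(!keep), length(keep)))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Kruskal-Wallis ANOVA on ranks with Dunn pairwise comparisons
#'
#' Compares a value across fat-category groups with the Kruskal-Wallis rank
#' test (tie-corrected) and follows up with Dunn's z tests on mean ranks,
#' Bonferroni-adjusted across all retained group pairs. Groups smaller than
#' `min_n` are dropped with a warning before testing, since their medians
#' are unstable (underweight groups are typically tiny because animals
#' without a defined CT fat peak cannot enter the analysis).
#'
#' @param data a data frame.
#' @param value tidy-eval column of the quantity compared.
#' @param group tidy-eval column of the grouping factor.
#' @param min_n smallest group size retained.
#' @return An object of class `group_comparison`: Kruskal-Wallis `statistic`
#'   (H), `df`, `p`, and a `pairwise` tibble with Dunn z and adjusted p per
#'   pair.
#' @export
compare_fc_groups <- function(data, value, group = visual_fc, min_n = 4) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  ok <- complete.cases(v, g)
  v <- v[ok]
  g <- g[ok]
  sizes <- table(g)
  small <- names(sizes)[sizes < max(min_n, 2)]
  if (length(small)) {
    warn(sprintf(
      "dropping group(s) below n = %d: %s",
      min_n, paste(small, collapse = ", ")
    ))
    keep <- !g %in% small
    v <- v[keep]
    g <- g[keep]
  }
  groups <- unique(g)
  if (length(groups) < 2) abort("fewer than two retained groups.")

  kw <- kruskal.test(v, factor(g))
  pairwise <- dunn_pairwise(v, g)
  structure(
    list(
      statistic = unname(kw$statistic),
      df = unname(kw$parameter),
      p = kw$p.value,
      groups = sort(groups),
      n = length(v),
      pairwise = pairwise,
      data = tibble(value = v, group = g)
    ),
    class = "group_comparison"
  )
}

# Dunn's post-hoc z tests: differences of mean ranks over the pooled
# ranking, variance N(N+1)/12 minus the tie correction sum(t^3 - t) /
# (12 (N - 1)), Bonferroni-adjusted over all pairs.
dunn_pairwise <- function(v, g) {
  r <- rank(v)
  N <- length(v)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  groups <- sort(unique(g))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    ra <- r[g == pr[1]]
    rb <- r[g == pr[2]]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / length(ra) + 1 / length(rb)))
    z <- (mean(ra) - mean(rb)) / se
    tibble(
      group_a = pr[1], group_b = pr[2],
      z = z, p = 2 * pnorm(-abs(z))
    )
  })
  mutate(rows, adjusted_p = pmin(1, .data$p * length(pairs)))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> Kruskal-Wallis H = %.3f, df = %d, p = %.3g (n = %d)\n",
    x$statistic, x$df, x$p, x$n
  ))
  print(x$pairwise)
  invisible(x)
}

#' Join necropsy, FFR, and CT composition into one cohort table
#'
#' One row per animal; CT quantities may be missing for animals without a
#' usable CT study. Rows lacking both an FFPW and an nBFV are rejected.
#'
#' @param records necropsy tibble (see [read_records()]).
#' @param compositions tibble of [ct_composition()] rows (optional).
#' @return Cohort tibble keyed by `cat_id`, with `ffr` computed.
#' @export
build_cohort_table <- function(records, compositions = NULL) {
  out <- compute_ffr(validate_records(records))
  if (!is.null(compositions) && nrow(compositions)) {
    out <- left_join(out, as_tibble(compositions), by = "cat_id")
  }
  if (anyDuplicated(out$cat_id)) abort("`cat_id` must be unique.")
  has_nbfv <- "nbfv" %in% names(out) & !is.na(out[["nbfv"]] %||% NA)
  if (any(is.na(out$ffpw) & !has_nbfv)) {
    abort("every animal needs at least one of FFPW and nBFV.")
  }
  out
}
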