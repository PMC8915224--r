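#' Fixed regression coefficients for cutoff chaining
#'
#' A `regression_fit` holds the coefficients of a fitted (or fixed
#' reference) simple regression together with the transform under which it
#' was estimated: `"none"` (response on predictor), `"ln_ln"` (natural log
#' of both), or `"ln_y"` (log response only).
#'
#' `reference_fits()` returns the two fixed reference equations used for
#' cutoff chaining in the 39-cat feline validation cohort:
#' `ln(FFR) = -1.459 + 1.356 * ln(nBFV)`, and — with muscle-atrophic and
#' -hypertrophic animals excluded — `%BF = 10.697 + 3.655 * nBFV`.
#'
#' @param intercept,slope coefficients on the (possibly transformed) scale.
#' @param r Pearson correlation of the fit, if known.
#' @param p two-sided p value of the slope, if known.
#' @param transform one of `"none"`, `"ln_ln"`, `"ln_y"`.
#' @return An object of class `regression_fit`.
#' @export
regression_fit <- function(intercept, slope, r = NA_real_, p = NA_real_,
                           transform = c("none", "ln_ln", "ln_y")) {
  transform <- match.arg(transform)
  if (!is.na(r) && abs(r) > 1) abort("|r| cannot exceed 1.")
  structure(
    list(
      intercept = intercept, slope = slope,
      r = r, r2 = r^2, p = p, transform = transform
    ),
    class = "regression_fit"
  )
}

#' @rdname regression_fit
#' @export
reference_fits <- function() {
  list(
    ffr_on_nbfv = regression_fit(-1.459, 1.356, r = 0.897, transform = "ln_ln"),
    pbf_on_nbfv = regression_fit(10.697, 3.655, r = 0.974, transform = "none")
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  eqn <- switch(x$transform,
    none = sprintf("y = %.4g + %.4g * x", x$intercept, x$slope),
    ln_ln = sprintf("ln(y) = %.4g + %.4g * ln(x)", x$intercept, x$slope),
    ln_y = sprintf("ln(y) = %.4g + %.4g * x", x$intercept, x$slope)
  )
  cat(sprintf("<regression_fit> %s (r = %.3f)\n", eqn, x$r))
  invisible(x)
}

#' Lower nBFV cutoffs from fat-category medians
#'
#' The lower cutoff for overweight is the midpoint of the median nBFV of
#' normal-weight and of overweight animals; the lower cutoff for obesity is
#' the midpoint of the overweight and obese medians. Medians of even-length
#' samples are the mean of the two central order statistics.
#'
#' @param data a data frame with one row per animal.
#' @param nbfv column holding nBFV values (tidy-eval).
#' @param fc column holding the visual fat category (tidy-eval).
#' @return Named list with `nbfv_overweight` and `nbfv_obese`.
#' @export
derive_nbfv_cutoffs <- function(data, nbfv = nbfv, fc = visual_fc) {
  values <- dplyr::pull(data, {{ nbfv }})
  cats <- dplyr::pull(data, {{ fc }})
  med <- function(category) {
    v <- values[cats == category & !is.na(values)]
    if (!length(v)) {
      abort(sprintf("no animals in fat category '%s'; cannot derive cutoffs.", category),
        class = "felifat_error_empty_category"
      )
    }
    median(v)
  }
  m_norm <- med("normal")
  m_over <- med("overweight")
  m_obese <- med("obese")
  list(
    nbfv_overweight = (m_norm + m_over) / 2,
    nbfv_obese = (m_over + m_obese) / 2
  )
}

#' Map an nBFV cutoff onto another scale through a regression
#'
#' Evaluates the regression at the cutoff: for an `ln_ln` fit this is
#' `exp(intercept + slope * ln(x))`; for an untransformed fit,
#' `intercept + slope * x`. Full precision is returned; report to 1
#' decimal with [round_report()]-style rounding where the convention calls
#' for it.
#'
#' @param nbfv_cutoff cutoff on the nBFV scale (positive under a log fit).
#' @param fit a [regression_fit()].
#' @return The cutoff on the fit's response scale.
#' @export
chain_cutoff_through_regression <- function(nbfv_cutoff, fit) {
  switch(fit$transform,
    ln_ln = {
      if (any(nbfv_cutoff <= 0)) {
        abort("nBFV cutoff must be positive under a log-log fit.")
      }
      exp(fit$intercept + fit$slope * log(nbfv_cutoff))
    },
    ln_y = exp(fit$intercept + fit$slope * nbfv_cutoff),
    none = fit$intercept + fit$slope * nbfv_cutoff
  )
}

#' Assemble a full cutoff set
#'
#' Chains nBFV cutoffs through the FFR and %BF regressions to give the
#' complete set of lower cutoffs for overweight and obesity on all three
#' scales. FFR and %BF cutoffs are reported to 1 decimal (the scale on
#' which classification operates); full-precision values are kept as
#' attributes.
#'
#' @param nbfv_overweight,nbfv_obese lower nBFV cutoffs.
#' @param ffr_fit,pbf_fit [regression_fit()]s mapping nBFV to FFR and %BF;
#'   defaults are the fixed reference equations.
#' @return A list of class `cutoff_set`.
#' @export
cutoff_set <- function(nbfv_overweight, nbfv_obese,
                       ffr_fit = reference_fits()$ffr_on_nbfv,
                       pbf_fit = reference_fits()$pbf_on_nbfv) {
  if (nbfv_overweight >= nbfv_obese) {
    abort("the overweight cutoff must lie below the obesity cutoff.")
  }
  ffr_ow <- chain_cutoff_through_regression(nbfv_overweight, ffr_fit)
  ffr_ob <- chain_cutoff_through_regression(nbfv_obese, ffr_fit)
  pbf_ow <- chain_cutoff_through_regression(nbfv_overweight, pbf_fit)
  pbf_ob <- chain_cutoff_through_regression(nbfv_obese, pbf_fit)
  structure(
    list(
      nbfv_overweight = nbfv_overweight,
      nbfv_obese = nbfv_obese,
      ffr_overweight = round_report(ffr_ow, 1),
      ffr_obese = round_report(ffr_ob, 1),
      pbf_overweight = round_report(pbf_ow, 1),
      pbf_obese = round_report(pbf_ob, 1)
    ),
    full_precision = c(
      ffr_overweight = ffr_ow, ffr_obese = ffr_ob,
      pbf_overweight = pbf_ow, pbf_obese = pbf_ob
    ),
    class = "cutoff_set"
  )
}

#' @rdname cutoff_set
#' @details `reference_cutoffs()` returns the fixed cutoff set obtained in
#'   the validation cohort: nBFV 4.180 / 7.322, giving FFR 1.6 / 3.5 and
#'   %BF 27.1 / 37.4 for overweight / obesity.
#' @export
reference_cutoffs <- function() {
  cutoff_set(4.180, 7.322)
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf(
    "<cutoff_set> lower cutoffs  overweight / obese\n  nBFV %.3f / %.3f\n  FFR  %.1f / %.1f\n  %%BF  %.1f / %.1f\n",
    x$nbfv_overweight, x$nbfv_obese,
    x$ffr_overweight, x$ffr_obese,
    x$pbf_overweight, x$pbf_obese
  ))
  invisible(x)
}

#' Classify animals by FFR
#'
#' FFR at or above the obesity cutoff is obese; FFR in
#' `[overweight cutoff, obesity cutoff)` is overweight; anything below is
#' `not_overweight` (FFR alone cannot separate normal from underweight).
#' Both boundaries are closed on the left: an FFR exactly at a cutoff takes
#' the heavier class.
#'
#' @param ffr numeric FFR values (non-negative).
#' @param cutoffs a [cutoff_set()]; defaults to the reference cutoffs
#'   (FFR 1.6 / 3.5).
#' @return Ordered factor with levels not_overweight < overweight < obese.
#' @export
classify_by_ffr <- function(ffr, cutoffs = reference_cutoffs()) {
  if (any(ffr < 0, na.rm = TRUE)) abort("FFR cannot be negative.")
  cut(ffr,
    breaks = c(-Inf, cutoffs$ffr_overweight, cutoffs$ffr_obese, Inf),
    labels = ffr_class_levels(),
    right = FALSE, ordered_result = TRUE
  )
}
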