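# Shared fixtures, all generated in code.

# Small, fast phantom spec for unit tests (64^3 is reserved for the
# end-to-end recovery checks).
small_spec <- function(...) {
  phantom_spec(body_extent = c(32L, 32L, 32L), ...)
}

# Deterministic HU histogram of a Gaussian mixture: expected counts from
# the normal CDF over integer bins, no sampling. Modal bins are the
# component means by construction.
gaussian_mixture_hist <- function(means, weights, n_total = 1e6, sd = 10,
                                  lo = -250L, hi = 250L) {
  bins <- seq.int(lo, hi)
  counts <- numeric(length(bins))
  for (i in seq_along(means)) {
    counts <- counts + n_total * weights[i] *
      (pnorm(bins + 0.5, means[i], sd) - pnorm(bins - 0.5, means[i], sd))
  }
  counts <- round(counts)
  keep <- counts > 0
  structure(
    tibble::tibble(bin_value = as.integer(bins[keep]), count = as.integer(counts[keep])),
    class = c("hu_histogram", class(tibble::tibble())),
    window = c(lo = lo, hi = hi)
  )
}

# A hand-built peaks object, for thresholding tests that do not need peak
# detection.
fixed_peaks <- function(fat, lean) {
  structure(
    list(fat_peak_hu = fat, lean_peak_hu = lean, midpoint_hu = (fat + lean) / 2),
    class = "tissue_peaks"
  )
}

# Necropsy table with valid schema.
toy_records <- function(n = 6, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    cat_id = sprintf("t%02d", seq_len(n)),
    body_weight = round(runif(n, 2500, 8000)),
    ffpw = round(runif(n, 0, 150)),
    fl_pm = round(runif(n, 10, 13), 2),
    fl_ct = round(runif(n, 10, 13), 2),
    visual_fc = sample(c("underweight", "normal", "overweight", "obese"), n, TRUE),
    muscle_grade = sample(c("atrophic", "normal", "hypertrophic"), n, TRUE)
  )
}
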