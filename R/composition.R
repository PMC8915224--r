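#' Mask excludable regions to background air
#'
#' Sets excluded regions to -1024 HU, the sentinel used for everything
#' outside the body. For soft-tissue measurements the external
#' objects/table, non-aerated lung, and GI/bladder contents (labels 1-3)
#' are removed; for bone measurements, dense non-skeletal structures
#' (label 4: microchips, implants, mineralization, calculi) are removed in
#' addition.
#'
#' @param volume a [ct_volume()].
#' @param masks an [exclusion_masks()] of identical geometry.
#' @param purpose `"soft_tissue"` (labels 1-3) or `"bone"` (labels 1-4).
#' @return A new `ct_volume`; the input is not modified.
#' @export
apply_exclusions <- function(volume, masks, purpose = c("soft_tissue", "bone")) {
  purpose <- match.arg(purpose)
  if (!identical(dim(volume$hu), dim(masks$labels))) {
    abort("volume and masks must have identical dimensions.")
  }
  max_label <- if (purpose == "soft_tissue") 3L else 4L
  hu <- volume$hu
  hu[masks$labels >= 1L & masks$labels <= max_label] <- -1024L
  ct_volume(hu, volume$spacing, cat_id = volume$cat_id)
}

#' Integer HU frequency histogram over a window
#'
#' Counts voxels per integer HU value over `[lo, hi]`, inclusive at both
#' ends. The soft-tissue window used for fat/lean separation is
#' `[-250, 250]`.
#'
#' @param volume a [ct_volume()].
#' @param lo,hi window bounds in HU.
#' @return A tibble of class `hu_histogram` with columns `bin_value` and
#'   `count`, one row per occupied integer HU value; the window is kept as
#'   an attribute.
#' @export
build_histogram <- function(volume, lo = -250L, hi = 250L) {
  if (lo > hi) abort("`lo` must not exceed `hi`.")
  v <- volume$hu[volume$hu >= lo & volume$hu <= hi]
  tab <- table(v)
  out <- tibble(
    bin_value = as.integer(names(tab)),
    count = as.integer(tab)
  )
  structure(out,
    class = c("hu_histogram", class(out)),
    window = c(lo = as.integer(lo), hi = as.integer(hi))
  )
}

#' Locate the fat and lean tissue peaks and their midpoint
#'
#' Smooths the histogram counts with a centred moving average (default
#' window 11 HU), finds local maxima with topographic prominence at least
#' `min_prominence_frac` of the total count (default 0.2%, low enough to
#' keep a genuine fat peak from a 10-15% fat compartment while rejecting
#' smoothed noise fluctuations, which sit an order of magnitude lower) and pairwise separation of at
#' least `min_separation` HU, and returns the two largest as the fat
#' (lower HU) and lean (higher HU) peaks together with their midpoint.
#'
#' Histograms without two qualifying maxima — typically underweight animals
#' whose fat peak is not defined — raise an error of class
#' `felifat_error_undefined_fat_peak` carrying the number of peaks found,
#' so callers can record the animal as excluded rather than mis-segment it.
#'
#' @param hist an `hu_histogram` from [build_histogram()].
#' @param smooth_window moving-average width in HU bins (odd integer).
#' @param min_prominence_frac minimum peak prominence as a fraction of the
#'   total in-window count.
#' @param min_separation minimum HU distance between retained peaks.
#' @return A list of class `tissue_peaks` with `fat_peak_hu`,
#'   `lean_peak_hu`, and `midpoint_hu`.
#' @export
find_tissue_peaks <- function(hist, smooth_window = 11L,
                              min_prominence_frac = 0.002,
                              min_separation = 30L) {
  w <- attr(hist, "window")
  if (is.null(w)) w <- c(lo = min(hist$bin_value), hi = max(hist$bin_value))
  bins <- seq.int(w[["lo"]], w[["hi"]])
  counts <- numeric(length(bins))
  counts[match(hist$bin_value, bins)] <- hist$count
  total <- sum(counts)

  if (total > 0) {
    k <- rep(1 / smooth_window, smooth_window)
    smoothed <- as.numeric(stats::filter(counts, k, sides = 2))
    pad <- (smooth_window - 1L) / 2L
    # edge bins: average over the available part of the window
    for (i in seq_len(pad)) {
      smoothed[i] <- mean(counts[1:(i + pad)])
      j <- length(counts) - i + 1L
      smoothed[j] <- mean(counts[(j - pad):length(counts)])
    }
    peaks <- local_maxima(smoothed)
    prom <- vapply(peaks, function(p) peak_prominence(smoothed, p), numeric(1))
    keep <- prom >= min_prominence_frac * total
    peaks <- peaks[keep]
    heights <- smoothed[peaks]
    # enforce separation greedily, highest peak first
    ord <- order(heights, decreasing = TRUE)
    kept <- integer(0)
    for (p in peaks[ord]) {
      if (all(abs(bins[p] - bins[kept]) >= min_separation)) kept <- c(kept, p)
    }
  } else {
    kept <- integer(0)
  }

  if (length(kept) < 2L) {
    abort(
      sprintf(
        "undefined fat peak: found %d qualifying histogram peak(s), need 2.",
        length(kept)
      ),
      class = "felifat_error_undefined_fat_peak",
      n_peaks = length(kept)
    )
  }

  top2 <- sort(bins[kept[1:2]])
  structure(
    list(
      fat_peak_hu = top2[1],
      lean_peak_hu = top2[2],
      midpoint_hu = mean(top2)
    ),
    class = "tissue_peaks"
  )
}

# Indices of strict-or-plateau local maxima of a numeric vector.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  idx <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  # also admit plateaus that fall on the right only after equal run
  idx
}

# Topographic prominence: height above the higher of the two lowest points
# on the paths from the peak to the nearest higher terrain (or the edge).
peak_prominence <- function(y, p) {
  h <- y[p]
  left <- y[seq_len(p - 1)]
  right <- if (p < length(y)) y[(p + 1):length(y)] else numeric(0)
  higher_l <- which(left > h)
  base_l <- if (length(higher_l)) min(y[(max(higher_l) + 1):(p - 1)]) else min(c(left, h))
  higher_r <- which(right > h)
  base_r <- if (length(higher_r)) {
    min(y[(p + 1):(p + min(higher_r) - 1)])
  } else {
    min(c(right, h))
  }
  h - max(base_l, base_r)
}

#' @export
print.tissue_peaks <- function(x, ...) {
  cat(sprintf(
    "<tissue_peaks> fat %d HU, lean %d HU, midpoint %.1f HU\n",
    x$fat_peak_hu, x$lean_peak_hu, x$midpoint_hu
  ))
  invisible(x)
}

#' Split the soft-tissue window at the fat/lean midpoint
#'
#' Voxels with HU at or below the midpoint are fat; voxels above the
#' midpoint (up to the window top) are lean. The fat interval is closed at
#' the midpoint; for the usual half-integer midpoint this puts the floor
#' bin and everything below it on the fat side.
#'
#' @param hist an `hu_histogram` over the soft-tissue window.
#' @param peaks a [find_tissue_peaks()] result from the same histogram.
#' @return Named integer vector with `fat_voxels` and `lean_voxels`.
#' @export
classify_soft_tissue <- function(hist, peaks) {
  fat <- sum(hist$count[hist$bin_value <= peaks$midpoint_hu])
  lean <- sum(hist$count[hist$bin_value > peaks$midpoint_hu])
  c(fat_voxels = as.integer(fat), lean_voxels = as.integer(lean))
}

#' Count bone-attenuation voxels
#'
#' Voxels with HU of 350 or more are bone, provided bone-purpose exclusions
#' (dense non-skeletal objects) have already been applied.
#'
#' @param volume a [ct_volume()] with bone exclusions applied.
#' @param threshold bone HU threshold (inclusive).
#' @return Integer voxel count.
#' @export
count_bone <- function(volume, threshold = 350L) {
  sum(volume$hu >= threshold)
}

#' Body composition from compartment voxel counts
#'
#' Applies the five composition equations: voxel volume
#' `vv = pixel width x pixel length x slice thickness` (cm^3); body-fat
#' percentage `pbf = 100 * fat / (fat + lean)`; body-fat volume
#' `bfv = fat * vv`; total body bone volume `tbbv = bone * vv`; and the
#' size-normalized body-fat volume `nbfv = bfv / tbbv`, which is invariant
#' to voxel size.
#'
#' @param fat_voxels,lean_voxels,bone_voxels compartment counts.
#' @param spacing voxel dimensions in cm (length 3).
#' @param cat_id identifier for the output row.
#' @return One-row tibble with `cat_id`, the three counts, `vv`, `pbf`,
#'   `bfv`, `tbbv`, and `nbfv`.
#' @export
compute_composition <- function(fat_voxels, lean_voxels, bone_voxels,
                                spacing, cat_id = "cat") {
  if (fat_voxels + lean_voxels <= 0) {
    abort("no soft-tissue voxels: %BF denominator is zero.",
      class = "felifat_error_empty_compartment"
    )
  }
  if (bone_voxels <= 0) {
    abort("no bone voxels: nBFV denominator is zero.",
      class = "felifat_error_empty_compartment"
    )
  }
  vv <- voxel_volume(spacing)
  bfv <- fat_voxels * vv
  tbbv <- bone_voxels * vv
  tibble(
    cat_id = cat_id,
    fat_voxels = as.integer(fat_voxels),
    lean_voxels = as.integer(lean_voxels),
    bone_voxels = as.integer(bone_voxels),
    vv = vv,
    pbf = 100 * fat_voxels / (fat_voxels + lean_voxels),
    bfv = bfv,
    tbbv = tbbv,
    nbfv = bfv / tbbv
  )
}

#' Full CT body-composition pipeline for one animal
#'
#' Chains the composition steps: soft-tissue exclusions, the `[-250, 250]`
#' HU histogram, fat/lean peak detection and midpoint thresholding, bone
#' exclusions and the 350 HU bone count, and the composition equations.
#'
#' @param volume a [ct_volume()].
#' @param masks an [exclusion_masks()]; omit for an already-clean volume.
#' @param ... passed to [find_tissue_peaks()].
#' @return One-row tibble as from [compute_composition()].
#' @export
ct_composition <- function(volume, masks = NULL, ...) {
  soft <- if (is.null(masks)) volume else apply_exclusions(volume, masks, "soft_tissue")
  hist <- build_histogram(soft, -250L, 250L)
  peaks <- find_tissue_peaks(hist, ...)
  counts <- classify_soft_tissue(hist, peaks)
  bone_vol <- if (is.null(masks)) volume else apply_exclusions(volume, masks, "bone")
  bone <- count_bone(bone_vol)
  compute_composition(counts[["fat_voxels"]], counts[["lean_voxels"]], bone,
    volume$spacing,
    cat_id = volume$cat_id
  )
}
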