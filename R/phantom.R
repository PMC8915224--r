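#' Specify a synthetic cat CT phantom
#'
#' Builds the parameter set for one synthetic whole-body CT phantom: an
#' ellipsoidal soft-tissue body with an embedded cylindrical bone proxy
#' (a spine-like column), fat and lean voxels interleaved at a target
#' fraction, optional excludable contents (non-aerated lung, GI/bladder
#' contents, a metal implant), an optional examination-table slab outside
#' the body, and Gaussian HU noise. Background air is fixed at -1024 HU.
#'
#' Default tissue attenuations are -100 HU (fat), +60 HU (lean) and
#' +600 HU (bone) with SD 10 HU; feline fat and lean HU distributions are
#' not standardized, so these are declared parameters, not measurements.
#' Non-aerated lung defaults to -30 HU, between the fat and lean peaks,
#' where atelectatic lung attenuates and where failing to exclude it
#' measurably corrupts the body-fat percentage.
#'
#' @param cat_id identifier.
#' @param target_fat_fraction fraction of soft-tissue voxels that are fat,
#'   in `[0, 1]`.
#' @param body_extent integer length-3, voxels per axis.
#' @param voxel_spacing numeric length-3, cm per axis.
#' @param fat_hu_mean,lean_hu_mean,bone_hu_mean compartment HU means.
#' @param hu_sd additive Gaussian HU noise SD.
#' @param lung_hu_mean,gi_hu_mean,implant_hu,table_hu_mean HU of the
#'   optional regions.
#' @param include_lung,include_gi_contents,include_implant,include_table
#'   flags for the optional regions.
#' @param ffpw_slope falciform fat pad weight generated per cm^3 of true
#'   body-fat volume (g/cm^3).
#' @param ffpw_noise_sd additive Gaussian noise on the generated FFPW (g).
#' @param fl_base femur length (cm) of a phantom at the reference body size;
#'   generated FL scales linearly with the phantom's physical extent.
#' @param seed integer RNG seed for this phantom.
#' @param degenerate set `TRUE` to deliberately violate the peak-separation
#'   invariant (e.g. to emulate underweight cats without a defined fat
#'   peak); otherwise such a spec is rejected.
#'
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(cat_id = "phantom",
                         target_fat_fraction = 0.30,
                         body_extent = c(64L, 64L, 64L),
                         voxel_spacing = c(0.35, 0.35, 0.45),
                         fat_hu_mean = -100,
                         lean_hu_mean = 60,
                         bone_hu_mean = 600,
                         hu_sd = 10,
                         lung_hu_mean = -30,
                         gi_hu_mean = 20,
                         implant_hu = 3000,
                         table_hu_mean = 0,
                         include_lung = TRUE,
                         include_gi_contents = TRUE,
                         include_implant = FALSE,
                         include_table = TRUE,
                         ffpw_slope = 0.024,
                         ffpw_noise_sd = 9.5,
                         fl_base = 11.4,
                         seed = 1L,
                         degenerate = FALSE) {
  spec <- structure(
    list(
      cat_id = as.character(cat_id),
      target_fat_fraction = target_fat_fraction,
      body_extent = as.integer(body_extent),
      voxel_spacing = as.numeric(voxel_spacing),
      fat_hu_mean = fat_hu_mean, lean_hu_mean = lean_hu_mean,
      bone_hu_mean = bone_hu_mean, hu_sd = hu_sd,
      lung_hu_mean = lung_hu_mean, gi_hu_mean = gi_hu_mean,
      implant_hu = implant_hu, table_hu_mean = table_hu_mean,
      include_lung = isTRUE(include_lung),
      include_gi_contents = isTRUE(include_gi_contents),
      include_implant = isTRUE(include_implant),
      include_table = isTRUE(include_table),
      ffpw_slope = ffpw_slope, ffpw_noise_sd = ffpw_noise_sd,
      fl_base = fl_base, seed = as.integer(seed),
      degenerate = isTRUE(degenerate)
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (target_fat_fraction < 0 || target_fat_fraction > 1) {
      abort("`target_fat_fraction` must be in [0, 1].")
    }
    if (length(body_extent) != 3L || any(body_extent < 8L)) {
      abort("`body_extent` must be three integers >= 8.")
    }
    if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0)) {
      abort("`voxel_spacing` must be three positive lengths in cm.")
    }
    if (fat_hu_mean < -250 || lean_hu_mean > 250 || fat_hu_mean >= lean_hu_mean) {
      abort("fat and lean HU means must lie in [-250, 250] with fat < lean.")
    }
    if (bone_hu_mean < 350 + 3 * hu_sd) {
      abort("`bone_hu_mean` must be at least 350 + 3 * hu_sd so bone classifies as bone.")
    }
    if (!degenerate && (lean_hu_mean - fat_hu_mean) < 6 * hu_sd) {
      abort(
        "fat and lean peaks closer than 6 * hu_sd are not separable; set `degenerate = TRUE` to build such a phantom deliberately.",
        class = "felifat_error_degenerate_spec"
      )
    }
  })
  invisible(spec)
}

# Deterministic region geometry for a phantom spec. Returns an integer
# array coded 0 background, 1 table, 2 lung, 3 GI/bladder contents,
# 4 implant, 5 bone, 6 soft tissue. No RNG is consumed: compartment counts
# are fixed by the spec alone, which lets record-only cohorts skip voxel
# synthesis entirely.
phantom_geometry <- function(spec) {
  d <- spec$body_extent
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) / (0.42 * d[1])
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) / (0.42 * d[2])
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) / (0.42 * d[3])
  xc <- array(cx, dim = d)
  yc <- aperm(array(cy, dim = d[c(2, 1, 3)]), c(2, 1, 3))
  zc <- aperm(array(cz, dim = d[c(3, 1, 2)]), c(2, 3, 1))
  body <- (xc^2 + yc^2 + zc^2) <= 1

  geom <- array(0L, dim = d)
  geom[body] <- 6L

  # Spine proxy: a cylinder along the z axis sized so bone is ~5% of the
  # body, giving normalized body-fat volumes in the observed feline range.
  bone <- body & ((xc^2 + yc^2) <= 0.18^2) & (zc^2 <= 0.95)
  geom[bone] <- 5L

  if (spec$include_lung) {
    lung <- ((xc - 0.35)^2 + yc^2 + (zc - 0.55)^2) <= 0.28^2 & geom == 6L
    geom[lung] <- 2L
  }
  if (spec$include_gi_contents) {
    gi <- ((xc + 0.35)^2 + yc^2 + (zc + 0.45)^2) <= 0.30^2 & geom == 6L
    geom[gi] <- 3L
  }
  if (spec$include_implant) {
    ix <- round(d[1] * 0.5) + 0:2
    iy <- round(d[2] * 0.65) + 0:2
    iz <- round(d[3] * 0.5) + 0:2
    sub <- geom[ix, iy, iz]
    sub[sub == 6L] <- 4L
    geom[ix, iy, iz] <- sub
  }
  if (spec$include_table) {
    slab <- array(FALSE, dim = d)
    slab[, (d[2] - 1):d[2], ] <- TRUE
    slab <- slab & geom == 0L
    geom[slab] <- 1L
  }
  geom
}

#' Generate a synthetic cat CT phantom with known ground truth
#'
#' Realizes the geometry described by a [phantom_spec()] into a noisy HU
#' volume, exclusion masks, and a ground-truth record of exact compartment
#' counts and derived quantities (true BFV, TBBV, nBFV, and generated
#' necropsy measurements).
#'
#' Fat and lean voxels are interleaved by seeded sampling so that the fat
#' share of soft tissue equals `round(target * n_soft) / n_soft`, within
#' 0.01 of the target. Identical spec and seed give bitwise-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([ct_volume()]), `masks`
#'   ([exclusion_masks()]), and `truth` (one-row tibble).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  counts <- phantom_truth_counts(spec, geom)

  set.seed(spec$seed)
  soft_idx <- which(geom == 6L)
  fat_idx <- sample(soft_idx, counts$true_fat_voxels)

  hu <- array(-1024, dim = spec$body_extent)
  noisy <- function(idx, mean_hu) {
    mean_hu + rnorm(length(idx), sd = spec$hu_sd)
  }
  hu[soft_idx] <- noisy(soft_idx, spec$lean_hu_mean)
  hu[fat_idx] <- noisy(fat_idx, spec$fat_hu_mean)
  for (reg in list(
    list(code = 5L, mean = spec$bone_hu_mean),
    list(code = 2L, mean = spec$lung_hu_mean),
    list(code = 3L, mean = spec$gi_hu_mean),
    list(code = 1L, mean = spec$table_hu_mean)
  )) {
    idx <- which(geom == reg$code)
    if (length(idx)) hu[idx] <- noisy(idx, reg$mean)
  }
  imp <- which(geom == 4L)
  if (length(imp)) hu[imp] <- spec$implant_hu
  hu <- pmax(round_half_away(hu), -1024)
  storage.mode(hu) <- "integer"

  labels <- array(0L, dim = spec$body_extent)
  for (code in 1:4) labels[geom == code] <- code

  truth <- phantom_truth(spec, counts)
  list(
    volume = ct_volume(hu, spec$voxel_spacing, cat_id = spec$cat_id),
    masks = exclusion_masks(labels),
    truth = truth
  )
}

phantom_truth_counts <- function(spec, geom = phantom_geometry(spec)) {
  n_soft <- sum(geom == 6L)
  n_bone <- sum(geom == 5L)
  n_fat <- as.integer(round(spec$target_fat_fraction * n_soft))
  list(
    true_fat_voxels = n_fat,
    true_lean_voxels = n_soft - n_fat,
    true_bone_voxels = n_bone
  )
}

# FL scales linearly with the phantom's physical extent; the reference size
# is the default 64-voxel geometry at (0.35, 0.35, 0.45) cm spacing.
phantom_fl <- function(spec) {
  size <- prod(spec$body_extent * spec$voxel_spacing)^(1 / 3)
  ref <- prod(c(64, 64, 64) * c(0.35, 0.35, 0.45))^(1 / 3)
  spec$fl_base * size / ref
}

phantom_truth <- function(spec, counts) {
  vv <- voxel_volume(spec$voxel_spacing)
  true_bfv <- counts$true_fat_voxels * vv
  true_tbbv <- counts$true_bone_voxels * vv
  set.seed(derive_seed(spec$seed, 1L))
  ffpw <- spec$ffpw_slope * true_bfv + rnorm(1, sd = spec$ffpw_noise_sd)
  ffpw <- max(0, round_half_away(ffpw))
  tibble(
    cat_id = spec$cat_id,
    true_fat_voxels = counts$true_fat_voxels,
    true_lean_voxels = counts$true_lean_voxels,
    true_bone_voxels = counts$true_bone_voxels,
    true_bfv = true_bfv,
    true_tbbv = true_tbbv,
    true_nbfv = true_bfv / true_tbbv,
    generated_ffpw = ffpw,
    generated_fl = round_report(phantom_fl(spec), 2)
  )
}

# Visual fat-category bands applied to the true fat fraction of soft
# tissue. Fixed, so category-agreement machinery can be exercised against a
# known assignment.
fc_from_fraction <- function(f) {
  cut(f,
    breaks = c(-Inf, 0.15, 0.27, 0.40, Inf),
    labels = c("underweight", "normal", "overweight", "obese"),
    right = FALSE
  ) |> as.character()
}

#' Generate a cohort of phantoms with matched necropsy records
#'
#' Draws `n_cats` phantoms with target fat fractions uniform over
#' `fat_fraction_range` and per-cat body sizes jittered by +/-15%, then
#' emits matched necropsy records: FFPW generated as
#' `ffpw_slope * true_bfv + noise`, floored at 0 g and rounded to integer
#' grams (below-scale weights are kept as 0 and flagged); FL scaled with
#' the phantom's physical extent and rounded to 2 decimals; a visual fat
#' category assigned from the true fat fraction via fixed bands
#' (<0.15 underweight, <0.27 normal, <0.40 overweight, else obese); and a
#' muscle grade sampled with realistic frequencies (atrophy is common in
#' cats presented for necropsy).
#'
#' @param n_cats number of cats, at least 4 (all fat categories reachable).
#' @param fat_fraction_range length-2 interval inside `[0.05, 0.70]`.
#' @param seed integer; each cat receives a derived substream so cohorts
#'   are reproducible under subsetting.
#' @param body_extent voxels per axis for every phantom.
#' @param voxels if `FALSE`, skip HU volume synthesis and return truth and
#'   necropsy records only (compartment counts are deterministic given the
#'   geometry, so the records are identical either way).
#' @param ... further arguments passed to [phantom_spec()].
#' @return A list with `phantoms` (list of `generate_phantom()` triples, or
#'   `NULL` when `voxels = FALSE`), `truth` (tibble, one row per cat), and
#'   `records` (necropsy tibble).
#' @export
generate_cohort <- function(n_cats,
                            fat_fraction_range = c(0.10, 0.60),
                            seed = 1L,
                            body_extent = c(64L, 64L, 64L),
                            voxels = TRUE,
                            ...) {
  if (n_cats < 4) abort("`n_cats` must be at least 4 to span the fat categories.")
  if (fat_fraction_range[1] < 0.05 || fat_fraction_range[2] > 0.70 ||
    diff(fat_fraction_range) < 0) {
    abort("`fat_fraction_range` must be an interval within [0.05, 0.70].")
  }

  set.seed(derive_seed(seed, 0L))
  fracs <- runif(n_cats, fat_fraction_range[1], fat_fraction_range[2])
  size <- runif(n_cats, 0.85, 1.15)
  muscle <- sample(muscle_levels(), n_cats,
    replace = TRUE, prob = c(0.40, 0.58, 0.02)
  )

  specs <- purrr::map(seq_len(n_cats), function(i) {
    phantom_spec(
      cat_id = sprintf("cat%03d", i),
      target_fat_fraction = fracs[i],
      body_extent = body_extent,
      voxel_spacing = c(0.35, 0.35, 0.45) * size[i],
      seed = derive_seed(seed, i),
      ...
    )
  })

  phantoms <- NULL
  if (voxels) {
    phantoms <- purrr::map(specs, generate_phantom)
    truth <- purrr::map_dfr(phantoms, "truth")
  } else {
    truth <- purrr::map_dfr(specs, function(s) phantom_truth(s, phantom_truth_counts(s)))
  }

  true_frac <- truth$true_fat_voxels /
    (truth$true_fat_voxels + truth$true_lean_voxels)
  soft_cm3 <- (truth$true_fat_voxels + truth$true_lean_voxels +
    truth$true_bone_voxels) * purrr::map_dbl(specs, ~ voxel_volume(.x$voxel_spacing))

  records <- tibble(
    cat_id = truth$cat_id,
    body_weight = round_half_away(soft_cm3), # ~1 g/cm^3 tissue density
    ffpw = truth$generated_ffpw,
    fl_pm = truth$generated_fl,
    fl_ct = truth$generated_fl,
    visual_fc = fc_from_fraction(true_frac),
    muscle_grade = muscle,
    below_scale = truth$generated_ffpw == 0
  )

  list(phantoms = phantoms, truth = truth, records = records)
}
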