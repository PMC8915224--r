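test_that("exclusions set the right labels to background air", {
  hu <- array(60L, dim = c(4, 4, 4))
  hu[1, 1, 1] <- 3000L # implant
  hu[2, 1, 1] <- -30L # lung-range voxel
  labels <- array(0L, dim = c(4, 4, 4))
  labels[1, 1, 1] <- 4L
  labels[2, 1, 1] <- 2L
  vol <- ct_volume(hu, c(0.1, 0.1, 0.1))
  masks <- exclusion_masks(labels)

  bone_clean <- apply_exclusions(vol, masks, "bone")
  expect_identical(bone_clean$hu[1, 1, 1], -1024L)

  soft_clean <- apply_exclusions(vol, masks, "soft_tissue")
  expect_identical(soft_clean$hu[2, 1, 1], -1024L)
  expect_identical(soft_clean$hu[1, 1, 1], 3000L) # label 4 kept for soft tissue

  # all-zero mask is the identity
  none <- apply_exclusions(vol, exclusion_masks(array(0L, dim = c(4, 4, 4))), "bone")
  expect_identical(none$hu, vol$hu)
  # input untouched
  expect_identical(vol$hu[1, 1, 1], 3000L)

  expect_error(
    apply_exclusions(vol, exclusion_masks(array(0L, dim = c(3, 4, 4)))),
    "identical dimensions"
  )
})

test_that("excluding lung removes exactly its in-window voxels", {
  ph <- generate_phantom(small_spec(seed = 21, include_lung = TRUE))
  in_window <- function(v) sum(v$hu >= -250L & v$hu <= 250L)
  before <- in_window(ph$volume)
  after <- in_window(apply_exclusions(ph$volume, ph$masks, "soft_tissue"))
  lung_in_window <- sum(ph$masks$labels == 2L &
    ph$volume$hu >= -250L & ph$volume$hu <= 250L)
  gi_in_window <- sum(ph$masks$labels == 3L &
    ph$volume$hu >= -250L & ph$volume$hu <= 250L)
  table_in_window <- sum(ph$masks$labels == 1L &
    ph$volume$hu >= -250L & ph$volume$hu <= 250L)
  expect_identical(before - after, lung_in_window + gi_in_window + table_in_window)
  expect_gt(lung_in_window, 0L)
})

test_that("histograms are integer-binned and inclusive at both window ends", {
  vol <- ct_volume(array(60L, dim = c(2, 2, 2)), c(0.1, 0.1, 0.1))
  h <- build_histogram(vol)
  expect_identical(h$bin_value, 60L)
  expect_identical(h$count, 8L)

  hu <- array(c(-251L, -250L, 250L, 251L, 0L, 0L, 0L, 0L), dim = c(2, 2, 2))
  h2 <- build_histogram(ct_volume(hu, c(0.1, 0.1, 0.1)))
  expect_identical(sum(h2$count), 6L) # -251 and 251 fall outside
  expect_true(-250L %in% h2$bin_value)
  expect_true(250L %in% h2$bin_value)
  expect_false(-251L %in% h2$bin_value)

  # total equals brute-force count on a random phantom
  ph <- generate_phantom(small_spec(seed = 8))
  h3 <- build_histogram(ph$volume)
  expect_identical(sum(h3$count), sum(ph$volume$hu >= -250L & ph$volume$hu <= 250L))

  expect_error(build_histogram(vol, 10L, -10L), "lo")
})

test_that("tissue peaks are found at the modes with the midpoint between them", {
  h <- gaussian_mixture_hist(c(-100, 60), c(0.3, 0.7))
  pk <- find_tissue_peaks(h)
  expect_identical(pk$fat_peak_hu, -100L)
  expect_identical(pk$lean_peak_hu, 60L)
  expect_equal(pk$midpoint_hu, -20)

  # symmetric equal peaks
  pk2 <- find_tissue_peaks(gaussian_mixture_hist(c(-50, 50), c(0.5, 0.5)))
  expect_equal(pk2$midpoint_hu, 0)
})

test_that("a unimodal lean-only histogram raises the undefined-fat-peak error", {
  h <- gaussian_mixture_hist(60, 1)
  err <- expect_error(find_tissue_peaks(h), class = "felifat_error_undefined_fat_peak")
  expect_identical(err$n_peaks, 1L)
  # empty histogram: zero peaks
  empty <- gaussian_mixture_hist(60, 0)
  err2 <- expect_error(find_tissue_peaks(empty), class = "felifat_error_undefined_fat_peak")
  expect_identical(err2$n_peaks, 0L)
})

test_that("the fat interval is closed at the midpoint", {
  h <- structure(
    tibble::tibble(bin_value = c(-20L, -19L), count = c(5L, 7L)),
    class = c("hu_histogram", class(tibble::tibble())),
    window = c(lo = -250L, hi = 250L)
  )
  counts <- classify_soft_tissue(h, fixed_peaks(-60, 20)) # midpoint -20
  expect_identical(counts[["fat_voxels"]], 5L)
  expect_identical(counts[["lean_voxels"]], 7L)

  # half-integer midpoint: floor bin goes to fat
  counts2 <- classify_soft_tissue(h, fixed_peaks(-60, 21)) # midpoint -19.5
  expect_identical(counts2[["fat_voxels"]], 5L)

  empty <- structure(
    tibble::tibble(bin_value = integer(), count = integer()),
    class = c("hu_histogram", class(tibble::tibble())),
    window = c(lo = -250L, hi = 250L)
  )
  expect_identical(sum(classify_soft_tissue(empty, fixed_peaks(-100, 60))), 0L)
})

test_that("classification counts match exhaustive enumeration on a phantom", {
  ph <- generate_phantom(small_spec(seed = 13))
  soft <- apply_exclusions(ph$volume, ph$masks, "soft_tissue")
  h <- build_histogram(soft)
  pk <- find_tissue_peaks(h)
  counts <- classify_soft_tissue(h, pk)
  hu <- soft$hu
  expect_identical(
    counts[["fat_voxels"]],
    sum(hu >= -250L & hu <= pk$midpoint_hu)
  )
  expect_identical(
    counts[["lean_voxels"]],
    sum(hu > pk$midpoint_hu & hu <= 250L)
  )
  # conservation: fat + lean equals the in-window voxel count
  expect_identical(sum(counts), sum(hu >= -250L & hu <= 250L))
})

test_that("bone counting is inclusive at 350 HU and matches the label field", {
  hu <- array(-1024L, dim = c(2, 2, 2))
  hu[1, 1, 1] <- 350L
  hu[2, 1, 1] <- 349L
  expect_identical(count_bone(ct_volume(hu, c(0.1, 0.1, 0.1))), 1L)
  expect_identical(count_bone(ct_volume(array(-1024L, dim = c(2, 2, 2)), c(0.1, 0.1, 0.1))), 0L)

  ph <- generate_phantom(small_spec(seed = 17, include_implant = TRUE))
  bone_clean <- apply_exclusions(ph$volume, ph$masks, "bone")
  # at 25 noise SDs below the bone mean, misclassification is negligible
  expect_identical(count_bone(bone_clean), as.integer(ph$truth$true_bone_voxels))
  # without exclusions the implant would inflate the count
  expect_gt(count_bone(ph$volume), count_bone(bone_clean))
})

test_that("composition equations follow the printed arithmetic", {
  c1 <- compute_composition(500, 500, 100, c(0.1, 0.1, 0.1))
  expect_equal(c1$pbf, 50)

  expect_equal(voxel_volume(c(0.05, 0.05, 0.06)), 1.5e-4)

  c2 <- compute_composition(1e6, 1e6, 2e5, c(0.05, 0.048, 0.05))
  vv <- 0.05 * 0.048 * 0.05
  expect_equal(c2$vv, vv)
  c3 <- compute_composition(1e6, 5e5, 2e5, c(0.04, 0.05, 0.06))
  expect_equal(c3$bfv, 1e6 * 1.2e-4)
  expect_equal(c3$tbbv, 2e5 * 1.2e-4)
  expect_equal(c3$nbfv, 5.0)

  expect_error(compute_composition(0, 0, 10, c(0.1, 0.1, 0.1)),
    class = "felifat_error_empty_compartment"
  )
  expect_error(compute_composition(10, 10, 0, c(0.1, 0.1, 0.1)),
    class = "felifat_error_empty_compartment"
  )
})

test_that("nBFV is exactly invariant to isotropic voxel rescaling", {
  ph <- generate_phantom(small_spec(seed = 19))
  comp1 <- ct_composition(ph$volume, ph$masks)
  scaled <- ct_volume(ph$volume$hu, ph$volume$spacing * 3.7, cat_id = ph$volume$cat_id)
  comp2 <- ct_composition(scaled, ph$masks)
  expect_equal(comp1$nbfv, comp2$nbfv, tolerance = 1e-14)
  expect_equal(comp2$bfv, comp1$bfv * 3.7^3)
})

test_that("turning a lean voxel to fat attenuation never lowers %BF", {
  ph <- generate_phantom(small_spec(seed = 23))
  before <- ct_composition(ph$volume, ph$masks)
  hu <- ph$volume$hu
  idx <- which(ph$masks$labels == 0L & hu == 60L)[1:50]
  hu[idx] <- -100L
  after <- ct_composition(ct_volume(hu, ph$volume$spacing), ph$masks)
  expect_gte(after$pbf, before$pbf)
})

test_that("measured %BF and nBFV are strongly correlated across a cohort", {
  co <- generate_cohort(10, c(0.10, 0.60), seed = 31, body_extent = c(32L, 32L, 32L))
  comps <- purrr::map_dfr(co$phantoms, ~ ct_composition(.x$volume, .x$masks))
  expect_gt(cor(comps$pbf, comps$nbfv), 0.9)
})
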