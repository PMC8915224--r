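#' Configuration for an end-to-end phantom analysis run
#'
#' @param seed single integer; every random step in the run derives from it.
#' @param n_cats cohort size.
#' @param fat_fraction_range target fat-fraction interval for the cohort.
#' @param body_extent phantom grid size (voxels per axis).
#' @param n_underweight additional very-lean phantoms (fat fraction 0.02)
#'   appended to exercise the undefined-fat-peak exclusion path.
#' @param cutoff_mode `"reference"` uses the fixed cutoff set (nBFV
#'   4.180 / 7.322, hence FFR 1.6 / 3.5); `"derived"` recomputes nBFV
#'   cutoffs from the cohort's fat-category medians and chains them through
#'   the reference regressions.
#' @param peak_params list of [find_tissue_peaks()] parameters.
#' @param report_precision decimals used at the report layer.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_cats = 20L,
                       fat_fraction_range = c(0.10, 0.60),
                       body_extent = c(64L, 64L, 64L),
                       n_underweight = 0L,
                       cutoff_mode = c("reference", "derived"),
                       peak_params = list(
                         smooth_window = 11L,
                         min_prominence_frac = 0.002,
                         min_separation = 30L
                       ),
                       report_precision = list(ffr = 1L, pbf = 1L, ci = 2L)) {
  structure(
    list(
      seed = as.integer(seed), n_cats = as.integer(n_cats),
      fat_fraction_range = fat_fraction_range,
      body_extent = as.integer(body_extent),
      n_underweight = as.integer(n_underweight),
      cutoff_mode = match.arg(cutoff_mode),
      peak_params = peak_params,
      report_precision = report_precision
    ),
    class = "run_config"
  )
}

with_stage <- function(stage, cat_id, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "felifat_error_undefined_fat_peak")) stop(e)
    abort(
      sprintf(
        "pipeline stage '%s' failed%s: %s",
        stage, if (is.null(cat_id)) "" else paste0(" for ", cat_id),
        conditionMessage(e)
      ),
      class = "felifat_error_pipeline", parent = e
    )
  })
}

#' Run the full phantom-to-diagnostics pipeline
#'
#' Generates a phantom cohort, runs the CT composition pipeline per animal
#' (animals without a defined fat peak are recorded under `exclusions`,
#' mirroring how underweight cats drop out of CT fat estimation), computes
#' FFRs, derives or fixes the cutoff set, classifies every animal by FFR,
#' tallies diagnostic performance against the visual fat category for both
#' conditions, and fits the cohort regressions. All rounding happens at
#' the report layer; internal values keep full precision.
#'
#' @param config a [run_config()].
#' @return A list of class `run_report` with elements `config`,
#'   `compositions`, `exclusions`, `cohort` (joined per-cat table with FFR
#'   and FFR class), `cutoffs`, `performance` (obesity and overweight),
#'   `stats`, and `truth`.
#' @export
run_pipeline <- function(config = run_config()) {
  cohort <- with_stage("phantom_cohort", NULL, generate_cohort(
    config$n_cats, config$fat_fraction_range,
    seed = config$seed, body_extent = config$body_extent
  ))
  phantoms <- cohort$phantoms
  truth <- cohort$truth
  records <- cohort$records

  if (config$n_underweight > 0) {
    for (i in seq_len(config$n_underweight)) {
      spec <- phantom_spec(
        cat_id = sprintf("lean%02d", i),
        target_fat_fraction = 0.02,
        body_extent = config$body_extent,
        seed = derive_seed(config$seed, 9000L + i)
      )
      ph <- with_stage("phantom_underweight", spec$cat_id, generate_phantom(spec))
      phantoms <- c(phantoms, list(ph))
      truth <- bind_rows(truth, ph$truth)
      records <- bind_rows(records, tibble(
        cat_id = spec$cat_id,
        body_weight = round_half_away(
          sum(ph$truth$true_fat_voxels, ph$truth$true_lean_voxels, ph$truth$true_bone_voxels) *
            voxel_volume(spec$voxel_spacing)
        ),
        ffpw = ph$truth$generated_ffpw,
        fl_pm = ph$truth$generated_fl,
        fl_ct = ph$truth$generated_fl,
        visual_fc = "underweight",
        muscle_grade = "normal",
        below_scale = ph$truth$generated_ffpw == 0
      ))
    }
  }

  compositions <- list()
  exclusions <- list()
  for (ph in phantoms) {
    comp <- tryCatch(
      with_stage(
        "ct_composition", ph$volume$cat_id,
        rlang::exec(ct_composition, ph$volume, ph$masks, !!!config$peak_params)
      ),
      felifat_error_undefined_fat_peak = function(e) {
        structure(list(
          cat_id = ph$volume$cat_id,
          reason = conditionMessage(e),
          n_peaks = e$n_peaks
        ), class = "exclusion")
      }
    )
    if (inherits(comp, "exclusion")) {
      exclusions <- c(exclusions, list(comp))
    } else {
      compositions <- c(compositions, list(comp))
    }
  }
  compositions <- if (length(compositions)) bind_rows(compositions) else tibble()
  exclusions <- purrr::map_dfr(
    exclusions,
    ~ tibble(cat_id = .x$cat_id, reason = .x$reason, n_peaks = .x$n_peaks)
  )

  cohort_table <- with_stage(
    "cohort_table", NULL,
    build_cohort_table(records, compositions)
  )

  cutoffs <- with_stage("cutoffs", NULL, {
    if (config$cutoff_mode == "reference") {
      reference_cutoffs()
    } else {
      nb <- derive_nbfv_cutoffs(
        filter(cohort_table, !is.na(.data$nbfv)),
        nbfv, visual_fc
      )
      cutoff_set(nb$nbfv_overweight, nb$nbfv_obese)
    }
  })

  cohort_table <- mutate(cohort_table,
    ffr_class = classify_by_ffr(.data$ffr, cutoffs)
  )

  performance <- with_stage("diagnostics", NULL, list(
    obesity = sens_spec_with_ci(confusion_table(cohort_table, "obesity")),
    overweight = sens_spec_with_ci(confusion_table(cohort_table, "overweight"))
  ))

  stats <- with_stage("cohort_stats", NULL, {
    ct_rows <- filter(cohort_table, !is.na(.data$nbfv))
    truth_joined <- left_join(ct_rows, truth, by = "cat_id")
    out <- list(
      ffpw_on_bfv = correlate(truth_joined, bfv, ffpw, transform = "none"),
      ffr_on_nbfv = correlate(
        filter(ct_rows, .data$ffr > 0), nbfv, ffr,
        transform = "ln"
      )
    )
    fc_sizes <- table(ct_rows$visual_fc)
    if (sum(fc_sizes >= 4) >= 2) {
      out$nbfv_by_fc <- suppressWarnings(
        compare_fc_groups(ct_rows, nbfv, visual_fc)
      )
    }
    out
  })

  structure(
    list(
      config = config,
      truth = truth,
      compositions = compositions,
      exclusions = exclusions,
      cohort = cohort_table,
      cutoffs = cutoffs,
      performance = performance,
      stats = stats
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> seed %d: %d composed + %d excluded of %d cats; cutoffs FFR %.1f / %.1f (%s)\n",
    x$config$seed, nrow(x$compositions), nrow(x$exclusions),
    nrow(x$cohort), x$cutoffs$ffr_overweight, x$cutoffs$ffr_obese,
    x$config$cutoff_mode
  ))
  print(x$performance$obesity)
  print(x$performance$overweight)
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes the machine-readable report: per-cat compositions, exclusions
#' with reasons, the cohort table with FFR and class, the cutoff set,
#' diagnostic performance (rounded at the configured report precision),
#' and the regression summaries.
#'
#' @param report a [run_pipeline()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  prec <- report$config$report_precision
  perf <- function(p) {
    list(
      condition = p$condition, tp = p$tp, fp = p$fp, fn = p$fn, tn = p$tn,
      sensitivity = round_report(p$sensitivity, prec$ci),
      specificity = round_report(p$specificity, prec$ci),
      sens_ci = round_report(p$sens_ci, prec$ci),
      spec_ci = round_report(p$spec_ci, prec$ci),
      sens_band = band_label(p$sensitivity),
      spec_band = band_label(p$specificity)
    )
  }
  fit <- function(f) {
    list(
      intercept = f$intercept, slope = f$slope, r = f$r, r2 = f$r2,
      p = f$p, transform = f$transform, n = f$n
    )
  }
  out <- list(
    seed = report$config$seed,
    cutoff_mode = report$config$cutoff_mode,
    cohort_size = nrow(report$cohort),
    n_composed = nrow(report$compositions),
    n_excluded = nrow(report$exclusions),
    exclusions = report$exclusions,
    cutoffs = unclass(report$cutoffs),
    compositions = report$compositions,
    cohort = mutate(report$cohort,
      ffr = round_report(.data$ffr, prec$ffr),
      ffr_class = as.character(.data$ffr_class)
    ),
    performance = purrr::map(report$performance, perf),
    stats = purrr::map(
      report$stats[intersect(names(report$stats), c("ffpw_on_bfv", "ffr_on_nbfv"))],
      fit
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
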