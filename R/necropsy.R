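#' Falciform fat pad weight to femur length ratio (FFR)
#'
#' The FFR is the falciform fat pad weight in grams divided by the femur
#' length in centimetres (recorded to 2 decimals). Full precision is kept
#' internally; use [round_ffr()] at the reporting layer. An FFPW of 0 g
#' (below scale resolution) is a valid value and yields FFR 0.
#'
#' @param records a data frame with numeric columns `ffpw` (g) and
#'   `fl` (cm); see [read_records()].
#' @return The input as a tibble with an `ffr` column appended.
#' @export
compute_ffr <- function(records) {
  records <- as_tibble(records)
  if (!all(c("ffpw", "fl") %in% names(records))) {
    records <- resolve_fl(records)
  }
  if (any(is.na(records$fl) | records$fl <= 0)) {
    abort("every record needs a positive femur length (postmortem or CT).",
      class = "felifat_error_missing_fl"
    )
  }
  if (any(records$ffpw < 0)) abort("`ffpw` must be non-negative.")
  mutate(records, ffr = .data$ffpw / round_report(.data$fl, 2))
}

#' @rdname compute_ffr
#' @param ffr numeric FFR values.
#' @param digits decimals for reporting (the convention is 1).
#' @export
round_ffr <- function(ffr, digits = 1) {
  round_report(ffr, digits)
}

# Fills `fl` from the postmortem measurement, falling back to the CT
# measurement when the postmortem value is missing, and records the source.
resolve_fl <- function(records) {
  fl_pm <- if ("fl_pm" %in% names(records)) records$fl_pm else NA_real_
  fl_ct <- if ("fl_ct" %in% names(records)) records$fl_ct else NA_real_
  fl <- ifelse(!is.na(fl_pm), fl_pm, fl_ct)
  source <- ifelse(!is.na(fl_pm), "postmortem", "ct")
  source[is.na(fl)] <- NA_character_
  mutate(records, fl = fl, fl_source = source)
}

necropsy_columns <- function() {
  c("cat_id", "body_weight", "ffpw", "fl_pm", "fl_ct", "visual_fc", "muscle_grade")
}

#' Read and write necropsy record tables
#'
#' CSV round-trip for per-animal necropsy records. Required columns:
#' `cat_id`, `body_weight` (g), `ffpw` (g; 0 encodes below-scale),
#' `fl_pm` and `fl_ct` (femur length, cm, postmortem and CT; either may be
#' missing per row but not both), `visual_fc` (one of severe_underweight,
#' underweight, normal, overweight, obese), `muscle_grade` (atrophic,
#' normal, hypertrophic). On read, `fl` and `fl_source` are resolved
#' (postmortem value, CT fallback) and `below_scale` is flagged for 0 g
#' fat pads. Malformed rows are reported with their row numbers.
#'
#' @param path CSV file path.
#' @param records a necropsy tibble.
#' @return `read_records()` a validated tibble; `write_records()` the path,
#'   invisibly.
#' @export
read_records <- function(path) {
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      cat_id = readr::col_character(),
      body_weight = readr::col_double(),
      ffpw = readr::col_double(),
      fl_pm = readr::col_double(),
      fl_ct = readr::col_double(),
      visual_fc = readr::col_character(),
      muscle_grade = readr::col_character()
    )
  )
  validate_records(records)
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  readr::write_csv(
    select(as_tibble(records), dplyr::all_of(necropsy_columns())),
    path
  )
  invisible(path)
}

#' @rdname read_records
#' @export
validate_records <- function(records) {
  records <- as_tibble(records)
  missing_cols <- setdiff(necropsy_columns(), names(records))
  if (length(missing_cols)) {
    abort(paste0(
      "necropsy table lacks column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad_row <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      abort(
        sprintf("%s in row(s): %s", what, paste(rows, collapse = ", ")),
        class = "felifat_error_bad_record"
      )
    }
  }
  bad_row(
    !records$visual_fc %in% fc_levels(),
    sprintf(
      "unknown visual fat category (allowed: %s)",
      paste(fc_levels(), collapse = ", ")
    )
  )
  bad_row(!records$muscle_grade %in% muscle_levels(), "unknown muscle grade")
  bad_row(is.na(records$body_weight) | records$body_weight <= 0, "non-positive body weight")
  bad_row(is.na(records$ffpw) | records$ffpw < 0, "negative or missing FFPW")
  bad_row(is.na(records$fl_pm) & is.na(records$fl_ct), "femur length missing in both postmortem and CT fields")
  records <- resolve_fl(records)
  mutate(records, below_scale = .data$ffpw == 0)
}
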