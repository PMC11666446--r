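#' Read and write cohort CSV files
#'
#' The on-disk cohort format is an RFC-4180 CSV with one row per
#' subject-test and the header
#' `id, group, age, sex, height_m, mass_kg, speed_mph, grade_frac,
#' hr_rest, hr_peak, hrr, rer, vo2peak_ml_min`. Extra columns are
#' preserved verbatim. `hrr` may be omitted when `hr_rest` and `hr_peak`
#' are present, in which case it is derived as their difference.
#'
#' Reading performs unit sanity checks with actionable errors: heights
#' above 3 are treated as suspected centimetres, grades above 1 as
#' suspected percent (set `grade_percent = TRUE` to accept percent input,
#' which is then divided by 100), duplicate ids are rejected, and sex
#' must be the strings `"male"`/`"female"` (case-insensitive; integer
#' codes are rejected).
#'
#' @param path File path.
#' @param grade_percent Set to `TRUE` if `grade_frac` is recorded in
#'   percent (e.g. 11 instead of 0.11).
#' @return `read_cohort_csv()` returns a validated cohort tibble;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort_csv(generate_cohort(cohort_spec(n = 10), seed = 1), path)
#' read_cohort_csv(path)
#' @export
read_cohort_csv <- function(path, grade_percent = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(cohort, grade_percent = grade_percent)
}

#' @rdname read_cohort_csv
#' @param cohort A cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  if (!is.data.frame(cohort)) abort("`cohort` must be a data frame.")
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Validate a cohort table
#'
#' Checks the schema and unit invariants described in
#' [read_cohort_csv()] and returns the cohort as a tibble with `sex`
#' normalised to lowercase and `hrr` derived from the heart-rate columns
#' when absent.
#'
#' @inheritParams read_cohort_csv
#' @inheritParams write_cohort_csv
#' @return The validated tibble.
#' @export
validate_cohort <- function(cohort, grade_percent = FALSE) {
  cohort <- require_cohort_columns(
    cohort, c("id", "age", "sex", "height_m", "mass_kg")
  )
  if (anyDuplicated(cohort$id)) {
    dup <- unique(cohort$id[duplicated(cohort$id)])
    abort(paste0("Duplicate id(s): ", paste(head(dup, 5), collapse = ", "), "."))
  }
  cohort$sex <- normalize_sex(cohort$sex)
  check_numeric(cohort$age, "age", nonnegative = TRUE)
  check_numeric(cohort$mass_kg, "mass_kg", positive = TRUE)
  check_numeric(cohort$height_m, "height_m", positive = TRUE)
  if (any(cohort$height_m > 3)) {
    abort("`height_m` contains values above 3; heights look like centimetres. Divide by 100.")
  }
  if ("grade_frac" %in% names(cohort)) {
    if (grade_percent) cohort$grade_frac <- cohort$grade_frac / 100
    if (any(cohort$grade_frac > 1, na.rm = TRUE)) {
      abort("`grade_frac` contains values above 1; grades look like percent. Use fractions (0.11) or set `grade_percent = TRUE`.")
    }
    check_grade(cohort$grade_frac, "grade_frac")
  }
  if (!"hrr" %in% names(cohort) &&
      all(c("hr_rest", "hr_peak") %in% names(cohort))) {
    cohort$hrr <- cohort$hr_peak - cohort$hr_rest
  }
  if ("hrr" %in% names(cohort)) check_numeric(cohort$hrr, "hrr", nonnegative = TRUE)
  if ("speed_mph" %in% names(cohort)) {
    check_numeric(cohort$speed_mph, "speed_mph", nonnegative = TRUE)
  }
  if ("vo2peak_ml_min" %in% names(cohort)) {
    check_numeric(cohort$vo2peak_ml_min, "vo2peak_ml_min", positive = TRUE)
  }
  cohort
}

# sidecar metadata next to a generated cohort CSV: seed, spec, and the
# md5 of the CSV for provenance
write_cohort_meta <- function(spec, seed, csv_path) {
  meta <- list(
    package = "ebmscale",
    version = as.character(packageVersion("ebmscale")),
    seed = seed,
    csv_md5 = unname(tools::md5sum(csv_path)),
    spec = unclass(spec)
  )
  meta_path <- paste0(csv_path, ".meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(meta_path)
}
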