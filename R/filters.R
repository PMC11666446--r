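#' Apply the study inclusion filters to a cohort
#'
#' Retains subjects with a maximal-effort test (peak RER at or above
#' `rer_min`), age inside `age_range` and BMI inside `bmi_range` (all
#' bounds inclusive). BMI is taken from a `bmi` column when present and
#' derived from `mass_kg / height_m^2` otherwise.
#'
#' @param cohort A cohort tibble with columns `rer`, `age`, and either
#'   `bmi` or `mass_kg` + `height_m`.
#' @param rer_min Minimum peak respiratory exchange ratio (default 1.0).
#' @param age_range Inclusive age bounds in years (default 18-79).
#' @param bmi_range Inclusive BMI bounds in kg/m^2 (default 18.5-40).
#' @return The filtered tibble, with an `exclusions` attribute holding a
#'   per-criterion tally (a row can fail several criteria and is counted
#'   in each) retrievable with [exclusion_tally()].
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 200), seed = 1)
#' kept <- apply_inclusion_filters(cohort)
#' exclusion_tally(kept)
#' @export
apply_inclusion_filters <- function(cohort, rer_min = 1.0,
                                    age_range = c(18, 79),
                                    bmi_range = c(18.5, 40)) {
  cohort <- require_cohort_columns(cohort, c("rer", "age"))
  bmi <- cohort_bmi(cohort)
  ok_rer <- cohort$rer >= rer_min
  ok_age <- cohort$age >= age_range[1] & cohort$age <= age_range[2]
  ok_bmi <- bmi >= bmi_range[1] & bmi <= bmi_range[2]
  tally <- tibble::tibble(
    criterion = c("rer", "age", "bmi"),
    n_excluded = c(sum(!ok_rer), sum(!ok_age), sum(!ok_bmi))
  )
  out <- cohort[ok_rer & ok_age & ok_bmi, , drop = FALSE]
  attr(out, "exclusions") <- tally
  attr(out, "n_input") <- nrow(cohort)
  out
}

#' @rdname apply_inclusion_filters
#' @param x A cohort returned by `apply_inclusion_filters()`.
#' @export
exclusion_tally <- function(x) {
  t <- attr(x, "exclusions")
  if (is.null(t)) abort("`x` carries no exclusion tally; was it filtered?")
  t
}
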