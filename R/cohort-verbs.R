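#' Pipeable cohort verbs
#'
#' Data-frame-first helpers that append derived columns to a cohort table
#' (one row per subject-test, with the columns documented in
#' [read_cohort_csv()]). They are thin wrappers around the vectorised
#' equations and are designed to chain with the pipe:
#'
#' ```r
#' cohort |> add_ebm() |> add_workload() |> add_vo2_prediction()
#' ```
#'
#' * `add_ebm()` appends `ebm` (and `ebm_additive` if
#'   `method = "both"`).
#' * `add_workload()` appends `wl_mets` (EBM-based) or `wl_kokkinos`.
#' * `add_vo2_prediction()` appends `vo2_pred_ml_min` for the chosen
#'   standard (requires the workload inputs).
#'
#' @param data A cohort data frame with columns `mass_kg`, `height_m`,
#'   `sex`, `age` (and `speed_mph`, `grade_frac`, `hrr` for workload and
#'   prediction).
#' @param method For `add_ebm()`: `"allometric"` (default), `"additive"`,
#'   or `"both"`.
#' @param formula For `add_workload()`: `"ebm"` or `"kokkinos"`.
#' @inheritParams predict_vo2peak
#' @return The input as a tibble with the derived column(s) appended.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 20), seed = 1)
#' cohort |> add_ebm() |> add_workload() |> dplyr::glimpse()
#' @export
add_ebm <- function(data, method = c("allometric", "additive", "both"),
                    constants = ebm_constants()) {
  method <- match.arg(method)
  data <- require_cohort_columns(data, c("mass_kg", "height_m", "sex", "age"))
  if (method %in% c("allometric", "both")) {
    data$ebm <- ebm_allometric(data$mass_kg, data$height_m, data$sex,
                               data$age, constants)
  }
  if (method %in% c("additive", "both")) {
    val <- ebm_additive(data$mass_kg, data$height_m, data$sex, data$age,
                        constants)
    if (method == "additive") data$ebm <- val else data$ebm_additive <- val
  }
  data
}

#' @rdname add_ebm
#' @export
add_workload <- function(data, formula = c("ebm", "kokkinos"),
                         constants = ebm_constants()) {
  formula <- match.arg(formula)
  data <- require_cohort_columns(data, c("speed_mph", "grade_frac", "hrr"))
  if (formula == "ebm") {
    data$wl_mets <- workload_ebm(data$speed_mph, data$grade_frac, data$hrr,
                                 constants)
  } else {
    data$wl_kokkinos <- workload_kokkinos(
      convert_speed(data$speed_mph, constants = constants),
      data$grade_frac, constants
    )
  }
  data
}

#' @rdname add_ebm
#' @export
add_vo2_prediction <- function(data, standard = c("ebm", "mass"),
                               wl_formula = NULL,
                               constants = ebm_constants()) {
  standard <- match.arg(standard)
  data <- require_cohort_columns(
    data, c("mass_kg", "height_m", "sex", "age", "speed_mph", "grade_frac", "hrr")
  )
  data$vo2_pred_ml_min <- predict_vo2peak(
    data$mass_kg, data$height_m, data$sex, data$age,
    data$speed_mph, data$grade_frac, data$hrr,
    standard = standard, wl_formula = wl_formula, constants = constants
  )
  data
}

require_cohort_columns <- function(data, cols) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(paste0(
      "Cohort is missing required column(s): ",
      paste(missing, collapse = ", "), "."
    ))
  }
  tibble::as_tibble(data)
}

# bmi column if present, else derived from mass and height
cohort_bmi <- function(data) {
  if ("bmi" %in% names(data)) return(data$bmi)
  data <- require_cohort_columns(data, c("mass_kg", "height_m"))
  data$mass_kg / data$height_m^2
}
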