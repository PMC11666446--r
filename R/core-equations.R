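#' Exercise body mass (EBM), allometric form
#'
#' EBM is a body-size scaling metric for peak oxygen uptake that combines
#' body mass, height, sex, and age multiplicatively:
#' \deqn{EBM = Mass^{0.63} \times Height^{0.53} \times 1.16^{[male]} \times
#'   \exp(-0.39 \, fAge^2), \quad fAge = Age / 100.}
#' The product is evaluated in log space for numerical stability. All
#' arguments are vectorised; scalars are recycled.
#'
#' @param mass Body mass in kilograms, > 0.
#' @param height Height in metres, > 0.
#' @param sex Character vector, `"male"` or `"female"` (case-insensitive).
#' @param age Age in years, >= 0.
#' @param constants An [ebm_constants()] list.
#'
#' @return Numeric vector of EBM values (strictly positive).
#' @examples
#' ebm_allometric(76.6, 1.75, "male", 20)
#' @seealso [ebm_additive()] for the sex-specific linear approximation.
#' @export
ebm_allometric <- function(mass, height, sex, age,
                           constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  sex <- normalize_sex(sex)
  a <- recycle_args(mass = mass, height = height, sex = sex, age = age)
  check_numeric(a$mass, "mass", positive = TRUE)
  check_numeric(a$height, "height", positive = TRUE)
  check_numeric(a$age, "age", nonnegative = TRUE)
  fage <- a$age / 100
  exp(
    constants$mass_exp * log(a$mass) +
      constants$height_exp * log(a$height) +
      log(constants$male_factor) * (a$sex == "male") +
      constants$age_coef * fage^2
  )
}

#' Exercise body mass, additive approximation
#'
#' Sex-specific linear approximation to [ebm_allometric()], intended for
#' bedside use:
#' \deqn{EBM_{male} = -0.58 + 0.18\,Mass + 7.20\,Height - 0.08\,Age}
#' \deqn{EBM_{female} = -0.26 + 0.16\,Mass + 5.63\,Height - 0.06\,Age}
#' with mass in kg, height in m, and age in years. For extreme inputs the
#' linear form can turn non-positive; a warning is issued and the value
#' returned unchanged.
#'
#' @inheritParams ebm_allometric
#' @return Numeric vector of approximate EBM values.
#' @examples
#' ebm_additive(76.6, 1.75, "male", 20)
#' @export
ebm_additive <- function(mass, height, sex, age,
                         constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  sex <- normalize_sex(sex)
  a <- recycle_args(mass = mass, height = height, sex = sex, age = age)
  check_numeric(a$mass, "mass", positive = TRUE)
  check_numeric(a$height, "height", positive = TRUE)
  check_numeric(a$age, "age", nonnegative = TRUE)
  cm <- constants$additive_male
  cf <- constants$additive_female
  male <- a$sex == "male"
  out <- ifelse(
    male,
    cm[["intercept"]] + cm[["mass"]] * a$mass + cm[["height"]] * a$height +
      cm[["age"]] * a$age,
    cf[["intercept"]] + cf[["mass"]] * a$mass + cf[["height"]] * a$height +
      cf[["age"]] * a$age
  )
  if (any(out <= 0)) {
    warn("ebm_additive() produced non-positive values for extreme inputs; the allometric form is recommended outside the adult anthropometric range.")
  }
  out
}

#' Treadmill workload in METs (EBM-based equation)
#'
#' \deqn{WL = 2 + Sp \times (1.06 + 5.22 \times fGr) + 0.019 \times HRR}
#' with speed in mph, fractional grade as a fraction (0.11, not 11), and
#' heart-rate reserve (peak minus resting heart rate) in beats per minute.
#' The intercept of 2 METs reflects the reduced mechanical efficiency of
#' slow locomotion, so the value is always at least 2.
#'
#' @param speed Treadmill speed in miles per hour, >= 0.
#' @param grade Fractional grade in `[0, 1]`.
#' @param hrr Heart-rate reserve in beats per minute, >= 0.
#' @inheritParams ebm_allometric
#' @return Numeric vector of workloads in METs.
#' @examples
#' workload_ebm(speed = 5, grade = 0.10, hrr = 108)
#' @export
workload_ebm <- function(speed, grade, hrr, constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  a <- recycle_args(speed = speed, grade = grade, hrr = hrr)
  check_numeric(a$speed, "speed", nonnegative = TRUE)
  check_grade(a$grade, "grade")
  check_numeric(a$hrr, "hrr", nonnegative = TRUE)
  constants$wl_intercept +
    a$speed * (constants$wl_speed + constants$wl_speed_grade * a$grade) +
    constants$wl_hrr * a$hrr
}

#' Treadmill workload in METs (Kokkinos comparator)
#'
#' Literature comparator workload,
#' \deqn{WL = [Sp(m/min) \times (0.17 + 0.79 \times fGr) + 3.5] / 3.5,}
#' i.e. the classic speed-and-grade oxygen-cost estimate divided by one
#' MET. Note the speed unit is metres per minute; use
#' [convert_speed()] for mph inputs.
#'
#' @param speed_m_per_min Treadmill speed in metres per minute, >= 0.
#' @inheritParams workload_ebm
#' @return Numeric vector of workloads in METs (>= 1).
#' @examples
#' workload_kokkinos(129, 0.11)
#' workload_kokkinos(convert_speed(5), 0.10)
#' @export
workload_kokkinos <- function(speed_m_per_min, grade,
                              constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  a <- recycle_args(speed_m_per_min = speed_m_per_min, grade = grade)
  check_numeric(a$speed_m_per_min, "speed_m_per_min", nonnegative = TRUE)
  check_grade(a$grade, "grade")
  k <- constants$kokkinos
  (a$speed_m_per_min * (k[["speed"]] + k[["grade"]] * a$grade) + k[["rest"]]) /
    constants$met_ml_per_kg
}

#' Predict absolute VO2peak from a treadmill test
#'
#' The generalized equation `VO2peak = 11 x EBM x WL` (standard `"ebm"`)
#' or the conventional total-body-mass equation
#' `VO2peak = 3.5 x Mass x WL` (standard `"mass"`). Each standard defaults
#' to its own workload formula: the EBM standard uses [workload_ebm()]
#' (the equation it was derived with) and the mass standard uses the
#' literature [workload_kokkinos()] estimate; `wl_formula` overrides this
#' pairing.
#'
#' @inheritParams ebm_allometric
#' @inheritParams workload_ebm
#' @param standard `"ebm"` or `"mass"`.
#' @param wl_formula `"ebm"` or `"kokkinos"`; `NULL` (default) pairs each
#'   standard with its own formula as described above.
#' @return Numeric vector of predicted VO2peak in ml O2 per minute.
#' @examples
#' predict_vo2peak(84, 1.78, "male", 44, speed = 5.4, grade = 0.11, hrr = 112)
#' @export
predict_vo2peak <- function(mass, height, sex, age, speed, grade, hrr,
                            standard = c("ebm", "mass"), wl_formula = NULL,
                            constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  standard <- match.arg(standard)
  if (is.null(wl_formula)) {
    wl_formula <- if (standard == "ebm") "ebm" else "kokkinos"
  }
  wl_formula <- match.arg(wl_formula, c("ebm", "kokkinos"))
  wl <- switch(wl_formula,
    ebm = workload_ebm(speed, grade, hrr, constants),
    kokkinos = workload_kokkinos(convert_speed(speed, constants = constants),
                                 grade, constants)
  )
  if (standard == "ebm") {
    constants$ebm_met_constant *
      ebm_allometric(mass, height, sex, age, constants) * wl
  } else {
    check_numeric(mass, "mass", positive = TRUE)
    constants$met_ml_per_kg * mass * wl
  }
}

#' Index absolute VO2peak to a body-size scaler
#'
#' Divides absolute VO2peak (ml/min) by total mass, `mass^0.7`, or EBM.
#' With `met_display = TRUE` the result is further divided by the
#' MET-equivalent constant of the scaler (3.5 for mass, 11 for EBM) so
#' that values are displayed in METs; there is no MET display for the
#' `mass^0.7` comparator.
#'
#' @param vo2 Absolute VO2peak in ml O2 per minute, > 0.
#' @param mass Body mass in kg (required for the mass-based scalers).
#' @param ebm EBM values (required for `scaler = "ebm"`); compute with
#'   [ebm_allometric()].
#' @param scaler One of `"mass"`, `"mass_0p7"`, `"ebm"`.
#' @param met_display Divide by the scaler's MET constant (see Details).
#' @inheritParams ebm_allometric
#' @return Numeric vector of indexed VO2peak. Units: ml/kg/min for
#'   `"mass"`, ml/kg^0.7/min for `"mass_0p7"`, ml/min per EBM unit for
#'   `"ebm"`; METs when `met_display = TRUE`.
#' @examples
#' index_vo2peak(2747, mass = 78)
#' index_vo2peak(2747, mass = 78, met_display = TRUE)
#' @export
index_vo2peak <- function(vo2, mass = NULL, ebm = NULL,
                          scaler = c("mass", "mass_0p7", "ebm"),
                          met_display = FALSE,
                          constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  scaler <- match.arg(scaler)
  check_numeric(vo2, "vo2", positive = TRUE)
  if (scaler %in% c("mass", "mass_0p7")) {
    if (is.null(mass)) abort("`mass` is required for mass-based scalers.")
    check_numeric(mass, "mass", positive = TRUE)
  }
  out <- switch(scaler,
    mass = vo2 / mass,
    mass_0p7 = vo2 / mass^constants$mass_allometry_comparator_exp,
    ebm = {
      if (is.null(ebm)) abort("`ebm` is required for scaler = \"ebm\".")
      check_numeric(ebm, "ebm", positive = TRUE)
      vo2 / ebm
    }
  )
  if (met_display) {
    out <- switch(scaler,
      mass = out / constants$met_ml_per_kg,
      ebm = out / constants$ebm_met_constant,
      abort("No MET display constant is defined for scaler = \"mass_0p7\".")
    )
  }
  out
}

#' Lean-body-mass and body-cell-mass relations of EBM
#'
#' `lbm_equivalent()` returns the predicted value of `LBM^0.9` from the
#' through-origin relation `LBM^0.9 = 1.61 x EBM` (lean body mass in kg,
#' allometric exponent 0.9). `bcm_scale()` raises EBM to the power 1.11
#' (the inverse of 0.9) to display it on a non-allometric scale comparable
#' to measured body cell mass trajectories.
#'
#' @param ebm EBM values, > 0.
#' @inheritParams ebm_allometric
#' @return Numeric vector.
#' @examples
#' lbm_equivalent(23.6)
#' bcm_scale(23.6)
#' @export
lbm_equivalent <- function(ebm, constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  check_numeric(ebm, "ebm", positive = TRUE)
  constants$lbm_slope * ebm
}

#' @rdname lbm_equivalent
#' @export
bcm_scale <- function(ebm, constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  check_numeric(ebm, "ebm", positive = TRUE)
  ebm^constants$bcm_power
}

#' Unit conversions
#'
#' `convert_speed()` converts treadmill speed between miles per hour and
#' metres per minute using the exact factor 26.8224. `vo2_to_mets()`
#' converts absolute VO2peak (ml/min) to METs given body mass;
#' `relative_vo2_to_mets()` converts mass-relative VO2peak (ml/kg/min).
#'
#' @param speed Speed values, >= 0.
#' @param from,to `"mph"` or `"m_per_min"`.
#' @inheritParams ebm_allometric
#' @return Numeric vector in the requested unit.
#' @examples
#' convert_speed(1)                       # 26.8224 m/min
#' convert_speed(129, from = "m_per_min", to = "mph")
#' relative_vo2_to_mets(35.6)             # ~10.2 METs
#' @export
convert_speed <- function(speed, from = c("mph", "m_per_min"),
                          to = c("m_per_min", "mph"),
                          constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  from <- match.arg(from)
  to <- match.arg(to)
  check_numeric(speed, "speed", nonnegative = TRUE)
  if (from == to) return(speed)
  f <- constants$mph_to_m_per_min
  if (from == "mph") speed * f else speed / f
}

#' @rdname convert_speed
#' @param vo2 Absolute VO2peak in ml O2 per minute.
#' @param mass Body mass in kilograms.
#' @export
vo2_to_mets <- function(vo2, mass, constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  a <- recycle_args(vo2 = vo2, mass = mass)
  check_numeric(a$vo2, "vo2", nonnegative = TRUE)
  check_numeric(a$mass, "mass", positive = TRUE)
  a$vo2 / (constants$met_ml_per_kg * a$mass)
}

#' @rdname convert_speed
#' @param vo2_rel Mass-relative VO2peak in ml O2 per kg per minute.
#' @export
relative_vo2_to_mets <- function(vo2_rel, constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  check_numeric(vo2_rel, "vo2_rel", nonnegative = TRUE)
  vo2_rel / constants$met_ml_per_kg
}

#' Re-derive the MET-equivalent constant of the generalized equation
#'
#' The constant linking EBM units to ml O2 per minute per MET is obtained
#' from a reference individual (by default a 20-year-old man of height
#' 1.75 m and BMI 25, i.e. 76.6 kg): one MET costs `3.5 x mass` ml/min,
#' which divided by the individual's EBM and rounded to the nearest
#' integer gives 11.
#'
#' @inheritParams ebm_allometric
#' @return A one-row tibble with columns `ebm`, `unrounded`
#'   (ml/min/EBM/MET before rounding) and `constant` (the rounded
#'   integer).
#' @examples
#' recompute_met_constant()
#' @export
recompute_met_constant <- function(mass = 76.6, height = 1.75,
                                   sex = "male", age = 20,
                                   constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  ebm <- ebm_allometric(mass, height, sex, age, constants)
  unrounded <- constants$met_ml_per_kg * mass / ebm
  tibble::tibble(
    ebm = ebm,
    unrounded = unrounded,
    constant = as.integer(round(unrounded))
  )
}
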