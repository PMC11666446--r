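#' Scaling constants of the EBM and workload equations
#'
#' Bundles every published coefficient of the exercise-body-mass (EBM)
#' scaling system into a single immutable-by-default list: the allometric
#' EBM exponents, the sex-specific additive approximations, the treadmill
#' workload (WL) equation, the Kokkinos comparator workload, and the
#' unit-conversion factors. All downstream functions take a `constants`
#' argument so that any coefficient can be overridden for refit or
#' sensitivity experiments without touching package code.
#'
#' @details
#' The default values are:
#'
#' * `met_ml_per_kg` (3.5): oxygen cost of one metabolic equivalent of
#'   task (MET), ml O2 per kg per min.
#' * `ebm_met_constant` (11): ml O2 per min per EBM unit per MET; the
#'   MET-equivalent constant of the generalized equation
#'   `VO2peak = 11 x EBM x WL`.
#' * `mass_exp` (0.63), `height_exp` (0.53): allometric exponents on body
#'   mass (kg) and height (m).
#' * `male_factor` (1.16): multiplicative sex factor for men.
#' * `age_coef` (-0.39): coefficient on squared fractional age
#'   (fAge = age/100), applied inside the exponential.
#' * `additive_male`, `additive_female`: `(intercept, mass, height, age)`
#'   coefficients of the additive linear approximations to EBM.
#' * `wl_intercept` (2), `wl_speed` (1.06), `wl_speed_grade` (5.22),
#'   `wl_hrr` (0.019): the treadmill workload equation in METs,
#'   `WL = 2 + Sp(mph) x (1.06 + 5.22 x fGr) + 0.019 x HRR(bpm)`.
#' * `kokkinos` `(speed = 0.17, grade = 0.79, rest = 3.5)`: the comparator
#'   workload `[Sp(m/min) x (0.17 + 0.79 x fGr) + 3.5] / 3.5` METs.
#' * `mph_to_m_per_min` (26.8224): exact miles-per-hour to metres-per-minute
#'   factor.
#' * `lbm_slope` (1.61), `lbm_exp` (0.9): through-origin relation
#'   `LBM^0.9 = 1.61 x EBM` with lean body mass in kg.
#' * `bcm_power` (1.11): power (the inverse of 0.9) used to display EBM on
#'   a non-allometric body-cell-mass-like scale.
#' * `mass_allometry_comparator_exp` (0.7): exponent of the `Mass^0.7`
#'   comparator scaler.
#'
#' @param ... Named overrides of individual constants, e.g.
#'   `mass_exp = 0.7`. Unknown names are an error.
#' @param file Optional path to a JSON file of overrides with the same
#'   names (a flat object; the four-element vectors `additive_male`,
#'   `additive_female` and the three-element `kokkinos` may be given as
#'   arrays in documented order or as named objects). Overrides given via
#'   `...` take precedence over the file.
#'
#' @return A named list of class `ebm_constants`.
#' @examples
#' ebm_constants()$mass_exp
#' ebm_constants(mass_exp = 0.7)$mass_exp
#' @export
ebm_constants <- function(..., file = NULL) {
  defaults <- list(
    met_ml_per_kg = 3.5,
    ebm_met_constant = 11,
    mass_exp = 0.63,
    height_exp = 0.53,
    male_factor = 1.16,
    age_coef = -0.39,
    additive_male = c(intercept = -0.58, mass = 0.18, height = 7.20, age = -0.08),
    additive_female = c(intercept = -0.26, mass = 0.16, height = 5.63, age = -0.06),
    wl_intercept = 2,
    wl_speed = 1.06,
    wl_speed_grade = 5.22,
    wl_hrr = 0.019,
    kokkinos = c(speed = 0.17, grade = 0.79, rest = 3.5),
    mph_to_m_per_min = 26.8224,
    lbm_slope = 1.61,
    lbm_exp = 0.9,
    bcm_power = 1.11,
    mass_allometry_comparator_exp = 0.7
  )
  overrides <- list(...)
  if (!is.null(file)) {
    from_file <- jsonlite::read_json(file, simplifyVector = TRUE)
    # command-line overrides win over the file
    overrides <- modifyList(as.list(from_file), overrides)
  }
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm))) {
      abort("All constant overrides must be named.")
    }
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown)) {
      abort(paste0(
        "Unknown scaling constant(s): ", paste(unknown, collapse = ", "),
        ". See ?ebm_constants for the accepted names."
      ))
    }
    for (k in nm) {
      v <- unlist(overrides[[k]])
      tmpl <- defaults[[k]]
      if (length(v) != length(tmpl)) {
        abort(sprintf(
          "Constant '%s' must have length %d, got %d.", k, length(tmpl), length(v)
        ))
      }
      if (!is.null(names(tmpl))) {
        if (!is.null(names(v)) && all(nzchar(names(v)))) {
          bad <- setdiff(names(v), names(tmpl))
          if (length(bad)) {
            abort(sprintf(
              "Constant '%s': unknown component(s) %s.", k,
              paste(bad, collapse = ", ")
            ))
          }
          v <- v[names(tmpl)]
        }
        names(v) <- names(tmpl)
      }
      if (!is.numeric(v) || anyNA(v)) {
        abort(sprintf("Constant '%s' must be numeric and non-missing.", k))
      }
      defaults[[k]] <- v
    }
  }
  structure(defaults, class = "ebm_constants")
}

#' @export
print.ebm_constants <- function(x, ...) {
  cat("<ebm_constants>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (length(v) > 1L) {
      cat(sprintf("  %s: %s\n", k,
                  paste(sprintf("%s=%g", names(v), v), collapse = ", ")))
    } else {
      cat(sprintf("  %s: %g\n", k, v))
    }
  }
  invisible(x)
}

as_ebm_constants <- function(constants) {
  if (inherits(constants, "ebm_constants")) return(constants)
  if (is.null(constants)) return(ebm_constants())
  do.call(ebm_constants, as.list(constants))
}
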