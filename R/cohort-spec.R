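#' Specification of a synthetic cardiopulmonary-exercise cohort
#'
#' A `cohort_spec` bundles the distributional parameters from which
#' [generate_cohort()] draws a synthetic treadmill-CPX cohort. All
#' continuous variables are sampled from truncated normal distributions
#' (inverse-CDF sampling, so the output size is seed-stable), and
#' measured VO2peak is constructed from the generalized equation itself:
#' \deqn{VO2peak = s \times 11 \times EBM \times WL \times e^{\varepsilon},
#'   \quad \varepsilon \sim N(0, \sigma^2),}
#' where `s` is `hf_slope_factor` (1 for healthy cohorts, < 1 for heart
#' failure, reflecting a measured VO2peak that falls short of the
#' workload-predicted value).
#'
#' @section Presets:
#' Preset parameter sets reproduce the published summary statistics of a
#' large US treadmill-CPX registry:
#'
#' * `"healthy"` — apparently healthy adults: n = 5,618, 57% men, age
#'   44 (13) years, height 1.78 (0.07) m men / 1.65 (0.06) m women, BMI
#'   26 (4) truncated to 18.5-40, peak speed 5.4 (1.6) / 4.0 (1.1) mph,
#'   fractional grade 0.11 (0.05) / 0.12 (0.04), HRR 112 (17) / 103 (20)
#'   bpm, RER 1.17 (0.10).
#' * `"cvd"` — cardiovascular disease: n = 7,240, 74% men, age 57 (13),
#'   height 1.75/1.63 m, BMI 28 (4), speed 3.6 (1.0) / 3.2 (0.9) mph,
#'   grade 0.14 (0.03) / 0.12 (0.04), HRR 71 (22) / 72 (22), RER 1.15.
#' * `"hf"` — heart failure: the CVD parameters with n = 1,007 and
#'   `hf_slope_factor = 0.9`.
#' * `"dxa"` — a DXA body-composition cohort for lean-body-mass
#'   contextualisation: n = 466, 40% men, age 39 (7) truncated to 20-50,
#'   BMI 33 (4) truncated to 25-40 (a weight-loss-trial population).
#'
#' Only marginal means and SDs are published, so the joint structure is a
#' modelling choice: peak speed and HRR decline mildly with age
#' (`age_slope` mph/yr and bpm/yr on the conditional mean) and carry the
#' sex offsets implied by the sex-specific means; anthropometrics are
#' otherwise independent of the exercise variables.
#'
#' @param preset One of `"healthy"`, `"cvd"`, `"hf"`, `"dxa"`.
#' @param n Number of subjects (overrides the preset's n).
#' @param ... Named overrides of any spec field (see the field list in
#'   the return value); unknown fields are an error. Nested lists such as
#'   `age = list(mean = 50)` are merged into the preset values.
#' @param seed Default seed stored in the spec; `generate_cohort()`'s
#'   `seed` argument takes precedence.
#'
#' @return A list of class `cohort_spec` with fields `n`, `male_fraction`,
#'   `group`, `age`, `height`, `bmi`, `speed`, `grade`, `hrr`, `hr_rest`,
#'   `rer` (each a list of `mean`/`sd` and truncation bounds, by sex where
#'   applicable), `sigma` (log-scale SD of the VO2peak noise),
#'   `hf_slope_factor`, and `seed`.
#' @examples
#' cohort_spec()
#' cohort_spec("hf", n = 500)
#' cohort_spec(n = 100, sigma = 0, age = list(mean = 30))
#' @export
cohort_spec <- function(preset = c("healthy", "cvd", "hf", "dxa"),
                        n = NULL, ..., seed = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    healthy = list(
      n = 5618L, male_fraction = 0.57, group = "healthy",
      age = list(mean = 44, sd = 13, min = 18, max = 79),
      height = list(male = list(mean = 1.78, sd = 0.07),
                    female = list(mean = 1.65, sd = 0.06)),
      bmi = list(mean = 26, sd = 4, min = 18.5, max = 40),
      speed = list(male = list(mean = 5.4, sd = 1.6),
                   female = list(mean = 4.0, sd = 1.1),
                   age_slope = -0.02, min = 0),
      grade = list(male = list(mean = 0.11, sd = 0.05),
                   female = list(mean = 0.12, sd = 0.04),
                   min = 0, max = 0.4),
      hrr = list(male = list(mean = 112, sd = 17),
                 female = list(mean = 103, sd = 20),
                 age_slope = -0.5, min = 0),
      hr_rest = list(mean = 68, sd = 10, min = 40, max = 110),
      rer = list(mean = 1.17, sd = 0.10, min = 0.9),
      sigma = 0.17, hf_slope_factor = 1
    ),
    cvd = list(
      n = 7240L, male_fraction = 0.74, group = "cvd",
      age = list(mean = 57, sd = 13, min = 18, max = 79),
      height = list(male = list(mean = 1.75, sd = 0.07),
                    female = list(mean = 1.63, sd = 0.07)),
      bmi = list(mean = 28, sd = 4, min = 18.5, max = 40),
      speed = list(male = list(mean = 3.6, sd = 1.0),
                   female = list(mean = 3.2, sd = 0.9),
                   age_slope = -0.02, min = 0),
      grade = list(male = list(mean = 0.14, sd = 0.03),
                   female = list(mean = 0.12, sd = 0.04),
                   min = 0, max = 0.4),
      hrr = list(male = list(mean = 71, sd = 22),
                 female = list(mean = 72, sd = 22),
                 age_slope = -0.5, min = 0),
      hr_rest = list(mean = 71, sd = 10, min = 40, max = 110),
      rer = list(mean = 1.15, sd = 0.09, min = 0.9),
      sigma = 0.17, hf_slope_factor = 1
    ),
    hf = NULL, dxa = NULL
  )
  if (preset == "hf") {
    base <- cohort_spec("cvd")
    base$n <- 1007L
    base$group <- "hf"
    base$hf_slope_factor <- 0.9
    base <- unclass(base)
  }
  if (preset == "dxa") {
    base <- cohort_spec("healthy")
    base$n <- 466L
    base$male_fraction <- 0.4
    base$group <- "dxa"
    base$age <- list(mean = 39, sd = 7, min = 20, max = 50)
    base$bmi <- list(mean = 33, sd = 4, min = 25, max = 40)
    base <- unclass(base)
  }
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm))) abort("Spec overrides must be named.")
    unknown <- setdiff(nm, c(names(base), "seed", "n"))
    if (length(unknown)) {
      abort(paste0("Unknown cohort_spec field(s): ",
                   paste(unknown, collapse = ", "), "."))
    }
    base <- modifyList(base, overrides)
  }
  if (!is.null(n)) base$n <- n
  base$seed <- seed
  validate_cohort_spec(structure(base, class = "cohort_spec"))
}

validate_cohort_spec <- function(spec) {
  if (!is.numeric(spec$n) || length(spec$n) != 1L || spec$n < 1 ||
      spec$n != round(spec$n)) {
    abort("`n` must be a positive whole number.")
  }
  spec$n <- as.integer(spec$n)
  if (!is.numeric(spec$male_fraction) || spec$male_fraction < 0 ||
      spec$male_fraction > 1) {
    abort("`male_fraction` must lie in [0, 1].")
  }
  sds <- c(
    spec$age$sd, spec$bmi$sd, spec$hr_rest$sd, spec$rer$sd, spec$sigma,
    spec$height$male$sd, spec$height$female$sd,
    spec$speed$male$sd, spec$speed$female$sd,
    spec$grade$male$sd, spec$grade$female$sd,
    spec$hrr$male$sd, spec$hrr$female$sd
  )
  if (any(sds < 0)) abort("All spec standard deviations must be >= 0.")
  if (spec$hf_slope_factor <= 0 || spec$hf_slope_factor > 1) {
    abort("`hf_slope_factor` must lie in (0, 1].")
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> group=%s n=%d male_fraction=%.2f sigma=%.3g hf_slope_factor=%g\n",
    x$group, x$n, x$male_fraction, x$sigma, x$hf_slope_factor
  ))
  cat(sprintf("  age %g (%g) [%g, %g]; bmi %g (%g) [%g, %g]\n",
              x$age$mean, x$age$sd, x$age$min, x$age$max,
              x$bmi$mean, x$bmi$sd, x$bmi$min, x$bmi$max))
  invisible(x)
}

# Truncated-normal sampling by inverse CDF on the truncated range, so a
# fixed seed yields a fixed-size, bound-respecting sample.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (length(sd) == 1L && sd == 0) return(rep(mean, length.out = n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}
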