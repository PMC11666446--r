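#' Re-derive the EBM scaling exponents by log-linear backward regression
#'
#' Fits the multiplicative scaling model by regressing `ln(VO2peak)` on
#' `ln(mass)`, `ln(height)`, a male indicator, the fractional-age
#' polynomial `fAge`, `fAge^2`, `fAge^3` (`fAge = age/100`; an exact
#' reparameterisation of the raw age polynomial that keeps the design
#' well conditioned), and the exercise covariates speed, fractional grade
#' and heart-rate reserve. Terms with p above `p_remove` are removed
#' sequentially, one per iteration (worst p first; ties broken by larger
#' p then lexicographic term name). The retained log-scale coefficients
#' are exponentiated into the canonical multiplicative form
#' `Mass^a x Height^b x e^c(male) x exp(d x fAge^2)`.
#'
#' A sex-interaction check (nested F-test of the retained model against
#' the same model with all terms interacted with sex) is reported;
#' a significant test indicates that a common allometric model is not
#' adequate.
#'
#' @param cohort A cohort tibble (see [read_cohort_csv()] for columns)
#'   with `vo2peak_ml_min`.
#' @param p_remove Elimination threshold on the term p-value (default
#'   0.05).
#' @param workload `"linear"` (default) enters speed, grade and HRR as
#'   linear covariates, mirroring the original derivation on registry
#'   data. `"offset"` subtracts `ln(WL)` from the response instead
#'   (using the generator's latent workload when present, else
#'   [workload_ebm()]), which makes the model exactly identified on
#'   noiseless synthetic cohorts and is intended for simulation
#'   validation.
#' @param weights Optional non-negative case weights (the registry
#'   weighting is not reconstructible; the reproducible default is
#'   uniform).
#' @param constants An [ebm_constants()] list (used only for the
#'   `"offset"` workload).
#' @return An object of class `ebm_fit`: a list with elements `retained`
#'   (tibble of term, estimate, std.error, statistic, p.value),
#'   `eliminated` (tibble of step, term, p_exit), `canonical` (one-row
#'   tibble with `mass_exp`, `height_exp`, `male_factor`, `age_coef`,
#'   where `age_coef` multiplies `fAge^2`), `sex_interaction`,
#'   `r.squared`, `sigma`, `residuals` (mean, sd, Anderson-Darling
#'   normality statistic and p), `n`, and the underlying `model`.
#'   [tidy()] and [glance()] methods are provided.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 800), seed = 1)
#' fit <- fit_ebm_model(cohort)
#' fit$canonical
#' @export
fit_ebm_model <- function(cohort, p_remove = 0.05,
                          workload = c("linear", "offset"),
                          weights = NULL, constants = ebm_constants()) {
  workload <- match.arg(workload)
  constants <- as_ebm_constants(constants)
  cohort <- require_cohort_columns(
    cohort,
    c("mass_kg", "height_m", "sex", "age", "speed_mph", "grade_frac",
      "hrr", "vo2peak_ml_min")
  )
  sex <- normalize_sex(cohort$sex)
  fage <- cohort$age / 100
  df <- tibble::tibble(
    ln_mass = log(cohort$mass_kg),
    ln_height = log(cohort$height_m),
    male = as.numeric(sex == "male"),
    fage = fage, fage2 = fage^2, fage3 = fage^3,
    speed = cohort$speed_mph, grade = cohort$grade_frac, hrr = cohort$hrr
  )
  if (workload == "offset") {
    wl <- cohort$wl_latent %||%
      workload_ebm(cohort$speed_mph, cohort$grade_frac, cohort$hrr, constants)
    y <- log(cohort$vo2peak_ml_min) - log(wl)
    df <- df[, c("ln_mass", "ln_height", "male", "fage", "fage2", "fage3")]
  } else {
    y <- log(cohort$vo2peak_ml_min)
  }
  if (nrow(df) <= ncol(df) + 1L) {
    abort("Not enough rows to fit the scaling model.")
  }
  elim <- backward_eliminate(y, df, p_remove = p_remove, weights = weights)
  fit <- elim$fit
  retained <- elim$retained

  coef_or_zero <- function(term) {
    if (term %in% retained$term) {
      unname(retained$estimate[retained$term == term])
    } else {
      0
    }
  }
  canonical <- tibble::tibble(
    mass_exp = coef_or_zero("ln_mass"),
    height_exp = coef_or_zero("ln_height"),
    male_factor = exp(coef_or_zero("male")),
    age_coef = coef_or_zero("fage2")
  )
  sex_int <- sex_interaction_test(y, df, retained$term, weights)
  res <- stats::residuals(fit)
  ad <- tryCatch(nortest::ad.test(res),
                 error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  structure(
    list(
      model = fit,
      retained = retained,
      eliminated = elim$eliminated,
      canonical = canonical,
      sex_interaction = sex_int,
      r.squared = quiet_summary(fit)$r.squared,
      sigma = quiet_summary(fit)$sigma,
      residuals = tibble::tibble(
        mean = mean(res), sd = sd(res),
        ad_statistic = unname(ad$statistic), ad_p = unname(ad$p.value)
      ),
      n = nrow(df),
      p_remove = p_remove,
      workload = workload
    ),
    class = "ebm_fit"
  )
}

# summary.lm warns about "essentially perfect fit" on noiseless synthetic
# cohorts; exactness there is by construction, so the warning is muffled
quiet_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# Sequential backward elimination on a precomputed term data frame.
# Removes the single worst term with p > p_remove per iteration; ties are
# broken by the larger p then by lexicographic term name. The intercept
# is never removed. When the fit is numerically exact (residual variance
# below 1e-16 of the response variance) elimination stops: p-values carry
# no information at machine precision.
backward_eliminate <- function(y, df, p_remove, weights = NULL) {
  kept <- names(df)
  eliminated <- tibble::tibble(step = integer(), term = character(),
                               p_exit = numeric())
  step <- 0L
  repeat {
    dat <- cbind(.y = y, df[, kept, drop = FALSE])
    fit <- if (is.null(weights)) {
      lm(.y ~ ., data = dat)
    } else {
      dat$.w <- weights
      lm(.y ~ . - .w, data = dat, weights = .w)
    }
    if (anyNA(coef(fit))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      abort(paste0(
        "The design matrix is rank deficient; collinear term(s): ",
        paste(bad, collapse = ", "), "."
      ))
    }
    if (quiet_summary(fit)$sigma^2 < 1e-16 * max(var(y), .Machine$double.eps)) {
      break # exact fit: nothing left for p-values to rank
    }
    ct <- quiet_summary(fit)$coefficients
    ct <- ct[rownames(ct) != "(Intercept)", , drop = FALSE]
    p <- ct[, "Pr(>|t|)"]
    removable <- p[p > p_remove]
    if (!length(removable)) break
    ord <- order(-removable, names(removable))
    worst <- names(removable)[ord][1]
    step <- step + 1L
    eliminated <- dplyr::bind_rows(
      eliminated,
      tibble::tibble(step = step, term = worst, p_exit = unname(removable[worst]))
    )
    kept <- setdiff(kept, worst)
    if (!length(kept)) break
  }
  ct <- quiet_summary(fit)$coefficients
  retained <- tibble::tibble(
    term = rownames(ct),
    estimate = ct[, "Estimate"],
    std.error = ct[, "Std. Error"],
    statistic = ct[, "t value"],
    p.value = ct[, "Pr(>|t|)"]
  )
  retained <- retained[retained$term != "(Intercept)", , drop = FALSE]
  list(fit = fit, retained = retained, eliminated = eliminated, kept = kept)
}

# nested F-test of the retained model against the model with every
# retained (non-sex) term interacted with sex
sex_interaction_test <- function(y, df, retained_terms, weights = NULL) {
  base_terms <- union(retained_terms, "male")
  inter_terms <- setdiff(base_terms, "male")
  if (!length(inter_terms)) {
    return(list(p = NA_real_, significant = NA, note = "no terms to interact"))
  }
  dat <- cbind(.y = y, df[, base_terms, drop = FALSE])
  f_base <- as.formula(paste(".y ~", paste(base_terms, collapse = " + ")))
  f_full <- as.formula(paste(
    ".y ~", paste(base_terms, collapse = " + "), "+",
    paste(sprintf("male:%s", inter_terms), collapse = " + ")
  ))
  m_base <- lm(f_base, data = dat, weights = weights)
  m_full <- lm(f_full, data = dat, weights = weights)
  p <- tryCatch(anova(m_base, m_full)[2, "Pr(>F)"], error = function(e) NA_real_)
  list(p = p, significant = isTRUE(p < 0.05))
}

#' @export
print.ebm_fit <- function(x, ...) {
  cat(sprintf("EBM scaling model (n = %d, workload terms: %s)\n", x$n,
              x$workload))
  cat(sprintf("  R-squared %.3f, residual SD %.4f\n", x$r.squared, x$sigma))
  cat(sprintf(
    "  Canonical form: Mass^%.3f x Height^%.3f x %.3f(if male) x exp(%.3f x fAge^2)\n",
    x$canonical$mass_exp, x$canonical$height_exp, x$canonical$male_factor,
    x$canonical$age_coef
  ))
  if (nrow(x$eliminated)) {
    cat("  Eliminated:", paste(x$eliminated$term, collapse = ", "), "\n")
  }
  if (!is.na(x$sex_interaction$p)) {
    cat(sprintf("  Sex interaction F-test p = %.3g (%s)\n",
                x$sex_interaction$p,
                if (isTRUE(x$sex_interaction$significant)) "significant" else "not significant"))
  }
  invisible(x)
}

#' Re-derive the treadmill workload equation
#'
#' Regresses MET-standardised VO2peak, `VO2peak / (constant x EBM)`, on
#' the horizontal speed component, the vertical `speed x grade`
#' component, and heart-rate reserve, with an intercept. Backward
#' elimination removes terms with p above `p_remove` (the intercept is
#' always kept). On a noiseless synthetic cohort this reproduces the
#' generating coefficients `(2, 1.06, 5.22, 0.019)` exactly.
#'
#' @inheritParams fit_ebm_model
#' @param met_constant The MET-equivalent constant dividing VO2peak
#'   (default `constants$ebm_met_constant`, i.e. 11).
#' @param terms Subset of `c("speed", "speed_grade", "hrr")` to offer to
#'   the regression, e.g. drop `"hrr"` to quantify how the speed
#'   coefficients compensate for it.
#' @return An object of class `wl_fit` with elements `coefficients`
#'   (named vector over intercept/speed/speed_grade/hrr, 0 for terms not
#'   offered or eliminated), `retained`, `eliminated`, `r.squared`,
#'   `sigma`, `n`, `met_constant`, and `model`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 500, sigma = 0), seed = 1)
#' coef(fit_workload_equation(cohort))
#' @export
fit_workload_equation <- function(cohort, met_constant = NULL,
                                  p_remove = 0.05,
                                  terms = c("speed", "speed_grade", "hrr"),
                                  weights = NULL,
                                  constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  met_constant <- met_constant %||% constants$ebm_met_constant
  terms <- match.arg(terms, several.ok = TRUE)
  cohort <- require_cohort_columns(
    cohort,
    c("mass_kg", "height_m", "sex", "age", "speed_mph", "grade_frac",
      "hrr", "vo2peak_ml_min")
  )
  ebm <- ebm_allometric(cohort$mass_kg, cohort$height_m, cohort$sex,
                        cohort$age, constants)
  y <- cohort$vo2peak_ml_min / (met_constant * ebm)
  df <- tibble::tibble(
    speed = cohort$speed_mph,
    speed_grade = cohort$speed_mph * cohort$grade_frac,
    hrr = cohort$hrr
  )[, terms, drop = FALSE]
  elim <- backward_eliminate(y, df, p_remove = p_remove, weights = weights)
  all_terms <- c("speed", "speed_grade", "hrr")
  coefs <- setNames(numeric(4), c("intercept", all_terms))
  coefs["intercept"] <- coef(elim$fit)[["(Intercept)"]]
  for (t in elim$retained$term) {
    coefs[t] <- elim$retained$estimate[elim$retained$term == t]
  }
  structure(
    list(
      model = elim$fit,
      coefficients = coefs,
      retained = elim$retained,
      eliminated = elim$eliminated,
      r.squared = quiet_summary(elim$fit)$r.squared,
      sigma = quiet_summary(elim$fit)$sigma,
      n = nrow(df),
      met_constant = met_constant,
      terms_offered = terms
    ),
    class = "wl_fit"
  )
}

#' @export
coef.wl_fit <- function(object, ...) object$coefficients

#' @export
print.wl_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "Workload equation (n = %d, MET constant %g):\n  WL(METs) = %.3f + %.3f x Sp + %.3f x Sp x fGr + %.4f x HRR\n",
    x$n, x$met_constant, co["intercept"], co["speed"], co["speed_grade"],
    co["hrr"]
  ))
  cat(sprintf("  R-squared %.3f\n", x$r.squared))
  invisible(x)
}

#' Fit the additive (linear) approximation to allometric EBM
#'
#' For each sex, regresses EBM on mass, height and age by ordinary (or
#' weighted) least squares, reproducing the bedside additive equations.
#' The approximation is flagged valid when every per-sex R-squared
#' reaches `r2_threshold`.
#'
#' @inheritParams fit_ebm_model
#' @param ebm Optional response vector; by default the allometric EBM is
#'   computed from the cohort's anthropometrics.
#' @param r2_threshold Validity threshold on the per-sex R-squared
#'   (default 0.99).
#' @return An object of class `ebm_additive_fit` with `coefficients` (a
#'   tibble of sex, intercept, mass, height, age), `r.squared` (named by
#'   sex), `valid`, and per-sex models.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 400), seed = 2)
#' fit_additive_approximation(cohort)$coefficients
#' @export
fit_additive_approximation <- function(cohort, ebm = NULL, weights = NULL,
                                       r2_threshold = 0.99,
                                       constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  cohort <- require_cohort_columns(cohort,
                                   c("mass_kg", "height_m", "sex", "age"))
  sex <- normalize_sex(cohort$sex)
  if (is.null(ebm)) {
    ebm <- ebm_allometric(cohort$mass_kg, cohort$height_m, sex, cohort$age,
                          constants)
  }
  sexes <- intersect(c("male", "female"), unique(sex))
  fits <- lapply(sexes, function(s) {
    idx <- sex == s
    if (sum(idx) < 4) {
      abort(sprintf(
        "Insufficient data: %d %s subject(s); at least 4 are required per sex.",
        sum(idx), s
      ))
    }
    dat <- tibble::tibble(
      ebm = ebm[idx], mass = cohort$mass_kg[idx],
      height = cohort$height_m[idx], age = cohort$age[idx]
    )
    w <- if (is.null(weights)) NULL else weights[idx]
    lm(ebm ~ mass + height + age, data = dat, weights = w)
  })
  names(fits) <- sexes
  coefs <- purrr::map_dfr(sexes, function(s) {
    co <- coef(fits[[s]])
    tibble::tibble(
      sex = s, intercept = co[["(Intercept)"]], mass = co[["mass"]],
      height = co[["height"]], age = co[["age"]]
    )
  })
  r2 <- purrr::map_dbl(fits, ~ quiet_summary(.x)$r.squared)
  structure(
    list(
      coefficients = coefs,
      r.squared = r2,
      valid = all(r2 >= r2_threshold),
      r2_threshold = r2_threshold,
      models = fits,
      n = setNames(purrr::map_int(sexes, ~ sum(sex == .x)), sexes)
    ),
    class = "ebm_additive_fit"
  )
}

#' @export
print.ebm_additive_fit <- function(x, ...) {
  cat("Additive approximation to allometric EBM\n")
  for (i in seq_len(nrow(x$coefficients))) {
    co <- x$coefficients[i, ]
    cat(sprintf(
      "  %s: EBM = %.2f + %.2f Mass + %.2f Height + %.2f Age  (R2 = %.4f, n = %d)\n",
      co$sex, co$intercept, co$mass, co$height, co$age,
      x$r.squared[[co$sex]], x$n[[co$sex]]
    ))
  }
  cat(sprintf("  valid (all R2 >= %.2f): %s\n", x$r2_threshold, x$valid))
  invisible(x)
}
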