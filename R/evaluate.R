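# Validity framework: body-size independence by workload bin, calibration
# slopes by subgroup, effect-size contrasts, heart-failure slope analysis,
# and the workload-formula comparison.

# through-origin least squares: slope = sum(xy)/sum(x^2), with the usual
# no-intercept standard error
slope_through_origin <- function(x, y) {
  sxx <- sum(x^2)
  if (sxx == 0) return(list(slope = NA_real_, se = NA_real_))
  b <- sum(x * y) / sxx
  n <- length(x)
  se <- if (n > 1) sqrt(sum((y - b * x)^2) / (n - 1) / sxx) else NA_real_
  list(slope = b, se = se)
}

# Cohen's D with the pooled standard deviation; undefined (NA) when the
# pooled variance is zero
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) return(NA_real_)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

# Pearson correlation with the exact two-sided t-transform p-value on
# n - 2 df; r is NA under the zero-variance guard or when n < 3
pearson_r_p <- function(x, y) {
  n <- length(x)
  # the variance guard is relative: an exactly proportional cohort leaves
  # floating-point residue in the indexed values
  near_const <- function(v) sd(v) <= 1e-10 * max(abs(mean(v)), .Machine$double.eps)
  if (n < 3 || near_const(x) || near_const(y)) {
    return(list(n = n, r = NA_real_, p = NA_real_))
  }
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(n = n, r = r, p = 2 * pt(-abs(tstat), n - 2))
}

wl_bin_labels <- function(breaks) {
  k <- length(breaks)
  c(sprintf("<%g", breaks[1]),
    sprintf("%g-%g", breaks[-k], breaks[-1] - 0.1),
    sprintf(">=%g", breaks[k]))
}

assign_wl_bin <- function(wl, breaks) {
  labels <- wl_bin_labels(breaks)
  idx <- findInterval(wl, breaks) + 1L
  factor(labels[idx], levels = labels)
}

#' Body-size independence of indexed VO2peak by workload bin
#'
#' A scaler provides body-size-independent indexing when the indexed
#' value `VO2peak / scaler` shows no residual correlation with the scaler
#' itself. Because VO2peak also depends on exercise intensity, the check
#' is run within sex and within 1-MET workload bins (default bin edges 7
#' to 15 METs for men and 6 to 12 METs for women, binned on the
#' EBM-based workload). Within each cell the Pearson correlation between
#' the indexed value and the scaler is reported with its exact two-sided
#' t-transform p-value; cells are flagged significant at `sig_level`
#' (default 0.01, a display threshold acknowledging the multiplicity of
#' cells).
#'
#' @param cohort A cohort tibble with `vo2peak_ml_min` and the workload
#'   inputs.
#' @param scalers Any of `"mass"`, `"mass_0p7"`, `"ebm"`.
#' @param wl_formula Workload used to form the bins: `"ebm"` (default) or
#'   `"kokkinos"`.
#' @param breaks_male,breaks_female Interior bin edges in METs.
#' @param sig_level Display significance threshold.
#' @param constants An [ebm_constants()] list.
#' @return A tibble of class `independence_table` with columns `scaler`,
#'   `sex`, `wl_bin`, `n`, `r`, `p`, `significant`. Cells with fewer than
#'   3 subjects are emitted with `r = NA` and a warning.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 2000), seed = 1)
#' size_independence(cohort, scalers = c("mass", "ebm"))
#' @export
size_independence <- function(cohort,
                              scalers = c("mass", "mass_0p7", "ebm"),
                              wl_formula = c("ebm", "kokkinos"),
                              breaks_male = 7:15, breaks_female = 6:12,
                              sig_level = 0.01,
                              constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  scalers <- match.arg(scalers, several.ok = TRUE)
  wl_formula <- match.arg(wl_formula)
  cohort <- require_cohort_columns(
    cohort,
    c("sex", "mass_kg", "height_m", "age", "speed_mph", "grade_frac",
      "hrr", "vo2peak_ml_min")
  )
  sex <- normalize_sex(cohort$sex)
  wl <- switch(wl_formula,
    ebm = workload_ebm(cohort$speed_mph, cohort$grade_frac, cohort$hrr,
                       constants),
    kokkinos = workload_kokkinos(
      convert_speed(cohort$speed_mph, constants = constants),
      cohort$grade_frac, constants
    )
  )
  ebm <- ebm_allometric(cohort$mass_kg, cohort$height_m, sex, cohort$age,
                        constants)
  scaler_values <- list(
    mass = cohort$mass_kg,
    mass_0p7 = cohort$mass_kg^constants$mass_allometry_comparator_exp,
    ebm = ebm
  )
  rows <- purrr::map_dfr(scalers, function(sc) {
    sv <- scaler_values[[sc]]
    indexed <- cohort$vo2peak_ml_min / sv
    purrr::map_dfr(c("male", "female"), function(s) {
      idx <- sex == s
      if (!any(idx)) return(NULL)
      breaks <- if (s == "male") breaks_male else breaks_female
      bin <- assign_wl_bin(wl[idx], breaks)
      purrr::map_dfr(levels(bin), function(b) {
        in_bin <- bin == b
        res <- pearson_r_p(sv[idx][in_bin], indexed[idx][in_bin])
        tibble::tibble(scaler = sc, sex = s, wl_bin = b, n = res$n,
                       r = res$r, p = res$p)
      })
    })
  })
  small <- rows$n < 3
  if (any(small)) {
    warn(sprintf(
      "%d workload bin(s) hold fewer than 3 subjects; their correlation is undefined.",
      sum(small)
    ))
  }
  rows$significant <- !is.na(rows$p) & rows$p < sig_level
  structure(rows,
            class = c("independence_table", class(rows)),
            wl_formula = wl_formula, sig_level = sig_level)
}

#' Calibration slopes of measured versus predicted VO2peak by subgroup
#'
#' For each sex x age-band x BMI-band cell, reports the through-origin
#' least-squares slope of measured on predicted VO2peak together with a
#' 95% confidence interval and, as a secondary estimator, the mean of the
#' per-subject measured/predicted ratios. A slope of 1 indicates an
#' unbiased prediction; below 1 the measured VO2peak falls short of the
#' workload-based estimate. Default bands follow the conventional
#' clinical cuts: age < 40, 40-60, > 60 years; BMI < 25, 25-30, > 30
#' (middle bands closed on both sides).
#'
#' @inheritParams size_independence
#' @param standard `"ebm"` (generalized equation, `11 x EBM x WL`) or
#'   `"mass"` (conventional `3.5 x Mass x WL` with the Kokkinos
#'   workload); `wl_formula` overrides the workload pairing.
#' @param wl_formula Optional workload override passed to
#'   [predict_vo2peak()].
#' @param age_breaks,bmi_breaks Two cut points each.
#' @return A tibble of class `calibration_report` with one row per
#'   non-empty cell (`sex`, `age_band`, `bmi_band`, `n`, `slope`,
#'   `conf.low`, `conf.high`, `ratio_mean`). The overall through-origin
#'   slope, its correlation and n are stored as attributes and surfaced
#'   by [glance()].
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 2000), seed = 1)
#' cal <- calibration_slopes(cohort)
#' glance(cal)
#' @export
calibration_slopes <- function(cohort, standard = c("ebm", "mass"),
                               wl_formula = NULL,
                               age_breaks = c(40, 60),
                               bmi_breaks = c(25, 30),
                               constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  standard <- match.arg(standard)
  cohort <- require_cohort_columns(
    cohort,
    c("sex", "mass_kg", "height_m", "age", "speed_mph", "grade_frac",
      "hrr", "vo2peak_ml_min")
  )
  pred <- predict_vo2peak(
    cohort$mass_kg, cohort$height_m, cohort$sex, cohort$age,
    cohort$speed_mph, cohort$grade_frac, cohort$hrr,
    standard = standard, wl_formula = wl_formula, constants = constants
  )
  meas <- cohort$vo2peak_ml_min
  bands <- tibble::tibble(
    sex = normalize_sex(cohort$sex),
    age_band = band3(cohort$age, age_breaks),
    bmi_band = band3(cohort_bmi(cohort), bmi_breaks)
  )
  cells <- dplyr::group_by(
    dplyr::mutate(bands, .pred = pred, .meas = meas),
    .data$sex, .data$age_band, .data$bmi_band
  )
  out <- dplyr::summarise(
    cells,
    n = dplyr::n(),
    slope = slope_through_origin(.data$.pred, .data$.meas)$slope,
    se = slope_through_origin(.data$.pred, .data$.meas)$se,
    ratio_mean = mean(.data$.meas / .data$.pred),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    conf.low = .data$slope - 1.96 * .data$se,
    conf.high = .data$slope + 1.96 * .data$se
  )
  out <- dplyr::select(out, "sex", "age_band", "bmi_band", "n", "slope",
                       "conf.low", "conf.high", "ratio_mean")
  n_cells <- 2L * 3L * 3L
  if (nrow(out) < n_cells) {
    warn(sprintf("%d of %d sex x age x BMI cells are empty and omitted.",
                 n_cells - nrow(out), n_cells))
  }
  overall <- slope_through_origin(pred, meas)
  structure(
    out,
    class = c("calibration_report", class(out)),
    standard = standard,
    overall = list(slope = overall$slope, se = overall$se,
                   r = cor(pred, meas), n = length(pred))
  )
}

band3 <- function(x, breaks) {
  stopifnot(length(breaks) == 2)
  labels <- c(sprintf("<%g", breaks[1]),
              sprintf("%g-%g", breaks[1], breaks[2]),
              sprintf(">%g", breaks[2]))
  factor(
    ifelse(x < breaks[1], labels[1], ifelse(x <= breaks[2], labels[2], labels[3])),
    levels = labels
  )
}

#' @rdname ebmscale-tidiers
#' @method glance calibration_report
#' @export
glance.calibration_report <- function(x, ...) {
  ov <- attr(x, "overall")
  tibble::tibble(
    standard = attr(x, "standard"),
    slope = ov$slope, se = ov$se, r = ov$r, n = ov$n
  )
}

#' Effect-size contrasts of indexed VO2peak between subgroups
#'
#' Quantifies how much of the sex, obesity and age differences in
#' indexed cardiorespiratory fitness is attributable to the scaling
#' standard. For each contrast -- men vs women (restricted to BMI < 25),
#' normal weight vs obese (BMI < 25 vs > 30), younger vs older (age < 40
#' vs > 60) -- the MET-standardised indexed VO2peak
#' (`VO2peak / (3.5 x Mass)` or `VO2peak / (11 x EBM)`) is compared via
#' the relative mean ratio (group A mean over group B mean, percent) and
#' Cohen's D with the pooled SD.
#'
#' @inheritParams size_independence
#' @param standards Any of `"mass"`, `"ebm"`.
#' @return A tibble of class `contrast_report` with columns `contrast`,
#'   `standard`, `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `ratio_pct`, `cohens_d`. `cohens_d` is `NA` when the pooled
#'   variance is zero.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 2000), seed = 1)
#' subgroup_contrasts(cohort)
#' @export
subgroup_contrasts <- function(cohort, standards = c("mass", "ebm"),
                               constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  standards <- match.arg(standards, several.ok = TRUE)
  cohort <- require_cohort_columns(
    cohort, c("sex", "mass_kg", "height_m", "age", "vo2peak_ml_min")
  )
  sex <- normalize_sex(cohort$sex)
  bmi <- cohort_bmi(cohort)
  ebm <- ebm_allometric(cohort$mass_kg, cohort$height_m, sex, cohort$age,
                        constants)
  mets <- list(
    mass = cohort$vo2peak_ml_min / (constants$met_ml_per_kg * cohort$mass_kg),
    ebm = cohort$vo2peak_ml_min / (constants$ebm_met_constant * ebm)
  )
  groups <- list(
    sex = list(label = c("men (BMI<25)", "women (BMI<25)"),
               a = sex == "male" & bmi < 25,
               b = sex == "female" & bmi < 25),
    bmi = list(label = c("BMI<25", "BMI>30"),
               a = bmi < 25, b = bmi > 30),
    age = list(label = c("age<40", "age>60"),
               a = cohort$age < 40, b = cohort$age > 60)
  )
  out <- purrr::map_dfr(names(groups), function(g) {
    gr <- groups[[g]]
    if (!any(gr$a) || !any(gr$b)) {
      warn(sprintf("Contrast '%s' has an empty group and is omitted.", g))
      return(NULL)
    }
    purrr::map_dfr(standards, function(st) {
      a <- mets[[st]][gr$a]
      b <- mets[[st]][gr$b]
      tibble::tibble(
        contrast = g, standard = st,
        group_a = gr$label[1], group_b = gr$label[2],
        n_a = length(a), n_b = length(b),
        mean_a = mean(a), mean_b = mean(b),
        ratio_pct = 100 * mean(a) / mean(b),
        cohens_d = cohens_d(a, b)
      )
    })
  })
  structure(out, class = c("contrast_report", class(out)))
}

#' Compare calibration slopes between healthy and heart-failure cohorts
#'
#' Computes the overall measured-versus-predicted through-origin slope of
#' the generalized equation in each cohort and their ratio. In heart
#' failure the measured VO2peak typically falls short of the
#' workload-predicted value (anaerobic metabolism, sarcopenia, fluid
#' overload), so the HF slope is expected below the healthy one; the
#' result flags whether that is observed.
#'
#' @param healthy,hf Cohort tibbles.
#' @inheritParams calibration_slopes
#' @return A list of class `hf_slope_report` with `slopes` (tibble with
#'   one row per cohort), `ratio` (HF slope / healthy slope),
#'   `hf_lower` (logical), and the two full [calibration_slopes()]
#'   reports.
#' @examples
#' healthy <- generate_cohort(cohort_spec(n = 1000), seed = 1)
#' hf <- generate_cohort(cohort_spec("hf", n = 500), seed = 2)
#' hf_slope_analysis(healthy, hf)
#' @export
hf_slope_analysis <- function(healthy, hf, standard = "ebm",
                              wl_formula = NULL,
                              constants = ebm_constants()) {
  cal_h <- calibration_slopes(healthy, standard = standard,
                              wl_formula = wl_formula, constants = constants)
  cal_f <- calibration_slopes(hf, standard = standard,
                              wl_formula = wl_formula, constants = constants)
  gh <- glance(cal_h)
  gf <- glance(cal_f)
  slopes <- tibble::tibble(
    cohort = c("healthy", "hf"),
    slope = c(gh$slope, gf$slope),
    se = c(gh$se, gf$se),
    r = c(gh$r, gf$r),
    n = c(gh$n, gf$n)
  )
  structure(
    list(
      slopes = slopes,
      ratio = gf$slope / gh$slope,
      hf_lower = gf$slope < gh$slope,
      calibration_healthy = cal_h,
      calibration_hf = cal_f
    ),
    class = "hf_slope_report"
  )
}

#' @export
print.hf_slope_report <- function(x, ...) {
  cat("Heart-failure slope analysis (measured vs predicted VO2peak)\n")
  print(x$slopes)
  cat(sprintf("  HF / healthy slope ratio: %.3f (%s)\n", x$ratio,
              if (x$hf_lower) "HF slope is lower" else "HF slope is NOT lower"))
  invisible(x)
}

#' Compare the EBM-based and Kokkinos workload formulas
#'
#' Through-origin regression of the Kokkinos comparator workload on the
#' EBM-based workload over a cohort, with the mean difference
#' (`WL_ebm - WL_kokkinos`) profiled by decile of the EBM-based
#' workload. The EBM-based equation yields higher estimates at low
#' workloads (intercept 2 vs 1 MET), reflecting the reduced efficiency
#' of slow locomotion.
#'
#' @inheritParams size_independence
#' @param n_bins Number of quantile bins for the discrepancy profile.
#' @return A list of class `wl_comparison` with `slope` (through-origin
#'   slope of Kokkinos on EBM workload), `by_bin` (tibble of bin, n,
#'   mean workloads, mean difference) and `higher_at_low_wl` (logical:
#'   EBM workload exceeds Kokkinos in the lowest bin).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 1000), seed = 1)
#' compare_workload_formulas(cohort)$slope
#' @export
compare_workload_formulas <- function(cohort, n_bins = 10,
                                      constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  cohort <- require_cohort_columns(cohort,
                                   c("speed_mph", "grade_frac", "hrr"))
  wl_e <- workload_ebm(cohort$speed_mph, cohort$grade_frac, cohort$hrr,
                       constants)
  wl_k <- workload_kokkinos(
    convert_speed(cohort$speed_mph, constants = constants),
    cohort$grade_frac, constants
  )
  bin <- dplyr::ntile(wl_e, n_bins)
  by_bin <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin, wl_e, wl_k), bin),
    n = dplyr::n(),
    wl_ebm_mean = mean(wl_e),
    wl_kokkinos_mean = mean(wl_k),
    mean_diff = mean(wl_e - wl_k),
    .groups = "drop"
  )
  structure(
    list(
      slope = slope_through_origin(wl_e, wl_k)$slope,
      by_bin = by_bin,
      higher_at_low_wl = by_bin$mean_diff[1] > 0
    ),
    class = "wl_comparison"
  )
}

#' @export
print.wl_comparison <- function(x, ...) {
  cat(sprintf(
    "Workload comparison: WL_kokkinos = %.3f x WL_ebm (through origin)\n",
    x$slope
  ))
  cat(sprintf("  EBM workload higher in the lowest decile: %s\n",
              x$higher_at_low_wl))
  invisible(x)
}

#' Through-origin relation between EBM and measured lean body mass
#'
#' Fits `LBM^0.9 = slope x EBM` through the origin on a DXA cohort and
#' reports the slope with the Pearson correlation between the two sides.
#'
#' @param dxa A tibble from [generate_dxa_cohort()] (or any table with
#'   `mass_kg`, `height_m`, `sex`, `age`, `lbm_kg`).
#' @inheritParams size_independence
#' @return A one-row tibble with `slope`, `se`, `r`, `n`.
#' @examples
#' fit_lbm_relation(generate_dxa_cohort(seed = 1))
#' @export
fit_lbm_relation <- function(dxa, constants = ebm_constants()) {
  constants <- as_ebm_constants(constants)
  dxa <- require_cohort_columns(dxa,
                                c("mass_kg", "height_m", "sex", "age", "lbm_kg"))
  check_numeric(dxa$lbm_kg, "lbm_kg", positive = TRUE)
  if (any(dxa$lbm_kg >= dxa$mass_kg)) {
    abort("`lbm_kg` must be below total `mass_kg` for every record.")
  }
  ebm <- ebm_allometric(dxa$mass_kg, dxa$height_m, dxa$sex, dxa$age,
                        constants)
  y <- dxa$lbm_kg^constants$lbm_exp
  st <- slope_through_origin(ebm, y)
  tibble::tibble(slope = st$slope, se = st$se, r = cor(ebm, y),
                 n = nrow(dxa))
}
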