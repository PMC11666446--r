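test_that("evaluation statistics match brute-force oracles on toy tables", {
  set.seed(61)
  x <- runif(20, 50, 100)
  y <- 30 * x + rnorm(20, sd = 40)

  # Pearson r on a single bin against the covariance/sd definition
  toy <- tibble::tibble(
    id = sprintf("X%02d", 1:20), sex = "male", age = 40,
    height_m = 1.75, mass_kg = x,
    speed_mph = 5, grade_frac = 0.1, hrr = 100,
    vo2peak_ml_min = y
  )
  tab <- suppressWarnings(size_independence(toy, scalers = "mass", breaks_male = 100))
  row <- tab[tab$sex == "male" & tab$n == 20, ]
  expect_equal(row$r, oracle_pearson(x, y / x), tolerance = 1e-12)
  # exact t-transform p-value
  r <- row$r
  tstat <- r * sqrt(18 / (1 - r^2))
  expect_equal(row$p, 2 * pt(-abs(tstat), 18), tolerance = 1e-12)

  # through-origin slope against sum(xy)/sum(x^2)
  cal <- suppressWarnings(calibration_slopes(toy))
  pred <- predict_vo2peak(toy$mass_kg, toy$height_m, toy$sex, toy$age,
                          toy$speed_mph, toy$grade_frac, toy$hrr)
  expect_equal(glance(cal)$slope, oracle_slope_origin(pred, y),
               tolerance = 1e-12)

  # Cohen's D on a six-point toy table
  a <- c(8.1, 9.4, 10.2)
  b <- c(7.0, 7.7, 8.4)
  toy6 <- tibble::tibble(
    id = sprintf("Y%02d", 1:6), sex = "female",
    age = c(30, 30, 30, 70, 70, 70), height_m = 1.65, mass_kg = 70,
    vo2peak_ml_min = c(a, b) * 3.5 * 70
  )
  ct <- suppressWarnings(subgroup_contrasts(toy6, standards = "mass"))
  age_row <- ct[ct$contrast == "age", ]
  expect_equal(age_row$cohens_d, oracle_cohens_d(a, b), tolerance = 1e-12)
  expect_equal(age_row$ratio_pct, 100 * mean(a) / mean(b), tolerance = 1e-12)
})

test_that("degenerate proportional cohorts hit the zero-variance guard", {
  co <- constant_wl_cohort(n = 120, seed = 62)
  # identical workload and no noise: VO2peak is exactly proportional to
  # EBM, so the EBM-indexed value is constant within the single bin
  tab <- suppressWarnings(size_independence(co, scalers = "ebm",
                                            breaks_male = 100, breaks_female = 100))
  full_bins <- tab[tab$n > 0, ]
  expect_true(all(is.na(full_bins$r)))
  expect_true(all(!full_bins$significant))
})

test_that("bin partitions are complete and small bins warn instead of erroring", {
  co <- small_cohort(n = 800, seed = 63)
  tab <- suppressWarnings(size_independence(co, scalers = "mass"))
  sums <- tapply(tab$n, tab$sex, sum)
  expect_identical(unname(sums["male"]), sum(co$sex == "male"))
  expect_identical(unname(sums["female"]), sum(co$sex == "female"))

  tiny <- small_cohort(n = 12, seed = 64)
  expect_warning(size_independence(tiny, scalers = "mass"), "fewer than 3")
})

test_that("calibration slopes are exactly 1 when measurement equals prediction", {
  co <- generate_cohort(cohort_spec(n = 1000, sigma = 0), seed = 65)
  cal <- calibration_slopes(co, standard = "ebm")
  expect_true(all(abs(cal$slope - 1) < 1e-12))
  expect_true(all(abs(cal$ratio_mean - 1) < 1e-12))
  expect_equal(glance(cal)$slope, 1, tolerance = 1e-12)
  # cell sizes partition the cohort
  expect_identical(sum(cal$n), nrow(co))
})

test_that("heart-failure cohorts show the constructed slope deficit", {
  healthy <- generate_cohort(cohort_spec(n = 2000), seed = 66)
  hf <- generate_cohort(cohort_spec("hf", n = 1000), seed = 67)
  rep <- hf_slope_analysis(healthy, hf)
  expect_true(rep$hf_lower)
  expect_equal(rep$ratio, 0.9, tolerance = 0.02 / 0.9)

  # identical cohorts give a ratio of exactly 1
  same <- hf_slope_analysis(healthy, healthy)
  expect_equal(same$ratio, 1, tolerance = 1e-14)

  # the ratio estimate is stable in cohort size
  hf_big <- generate_cohort(cohort_spec("hf", n = 3000), seed = 68)
  rep_big <- hf_slope_analysis(healthy, hf_big)
  expect_lt(abs(rep_big$ratio - rep$ratio), 0.02)
})

test_that("contrasts collapse when groups are identical and shrink under the EBM standard", {
  # identical MET values in both age groups: ratio 100%, D undefined
  toy <- tibble::tibble(
    id = sprintf("Z%02d", 1:8), sex = rep(c("male", "female"), 4),
    age = rep(c(30, 70), each = 4), height_m = 1.7, mass_kg = 75,
    vo2peak_ml_min = 10 * 3.5 * 75
  )
  ct <- suppressWarnings(subgroup_contrasts(toy, standards = "mass"))
  age_row <- ct[ct$contrast == "age", ]
  expect_equal(age_row$ratio_pct, 100)
  expect_true(is.na(age_row$cohens_d))

  # on synthetic data the sex gap in indexed fitness narrows under EBM
  co <- generate_cohort(cohort_spec(n = 4000), seed = 69)
  ct2 <- subgroup_contrasts(co)
  sex_rows <- ct2[ct2$contrast == "sex", ]
  d_mass <- abs(sex_rows$cohens_d[sex_rows$standard == "mass"])
  d_ebm <- abs(sex_rows$cohens_d[sex_rows$standard == "ebm"])
  expect_lt(d_ebm, d_mass)
})

test_that("workload formulas diverge at rest and agree proportionally overall", {
  # at rest the EBM-based equation starts at 2 METs, the comparator at 1
  expect_equal(workload_ebm(0, 0, 0), 2)
  expect_equal(workload_kokkinos(0, 0), 1)

  co <- generate_cohort(cohort_spec(n = 3000), seed = 70)
  cmp <- compare_workload_formulas(co)
  expect_gt(cmp$slope, 0.8)
  expect_lt(cmp$slope, 1.0)
  expect_true(cmp$higher_at_low_wl)

  # workloads are mass-free: perturbing anthropometrics changes nothing
  co2 <- co
  co2$mass_kg <- co2$mass_kg * 1.5
  expect_equal(compare_workload_formulas(co2)$slope, cmp$slope)
})

test_that("autoplot methods return ggplot objects", {
  co <- small_cohort(n = 500, seed = 71)
  expect_s3_class(autoplot(suppressWarnings(size_independence(co))), "ggplot")
  expect_s3_class(autoplot(suppressWarnings(calibration_slopes(co))), "ggplot")
  expect_s3_class(autoplot(subgroup_contrasts(co)), "ggplot")
  expect_s3_class(autoplot(compare_workload_formulas(co)), "ggplot")
})
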