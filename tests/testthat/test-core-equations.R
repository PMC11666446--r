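test_that("allometric EBM collapses to unity and matches direct-power evaluation", {
  expect_equal(ebm_allometric(1, 1, "female", 0), 1.0)

  # independent oracle: direct power-product arithmetic (the implementation
  # works in log space)
  grid <- expand.grid(
    mass = c(45, 60, 76.6, 90, 120),
    height = c(1.5, 1.65, 1.75, 1.95),
    sex = c("male", "female"),
    age = c(0, 20, 44, 79),
    stringsAsFactors = FALSE
  )
  direct <- grid$mass^0.63 * grid$height^0.53 *
    ifelse(grid$sex == "male", 1.16, 1) * exp(-0.39 * (grid$age / 100)^2)
  got <- ebm_allometric(grid$mass, grid$height, grid$sex, grid$age)
  expect_true(all(abs(got - direct) / direct <= 1e-12))
  expect_true(all(got > 0))
})

test_that("EBM of the reference man is ~23.6, giving the MET constant 11", {
  ref <- ebm_allometric(76.6, 1.75, "male", 20)
  expect_equal(ref, 23.635, tolerance = 1e-4)
  expect_equal(round(3.5 * 76.6 / ref), 11)
  rc <- recompute_met_constant()
  expect_identical(rc$constant, 11L)
  expect_gt(rc$unrounded, 10.5)
  expect_lt(rc$unrounded, 11.5)
})

test_that("EBM is monotone in mass and height and declines with age; sex ratio is exactly 1.16", {
  mass <- seq(50, 110, by = 5)
  expect_true(all(diff(ebm_allometric(mass, 1.7, "female", 40)) > 0))
  height <- seq(1.5, 1.95, by = 0.05)
  expect_true(all(diff(ebm_allometric(70, height, "male", 40)) > 0))
  age <- seq(1, 79, by = 2)
  expect_true(all(diff(ebm_allometric(70, 1.7, "female", age)) < 0))
  ratio <- ebm_allometric(70, 1.7, "male", 40) /
    ebm_allometric(70, 1.7, "female", 40)
  expect_equal(ratio, 1.16, tolerance = 1e-14)
})

test_that("invalid subject inputs are rejected with named errors", {
  expect_error(ebm_allometric(-1, 1.7, "male", 30), "mass")
  expect_error(ebm_allometric(70, 0, "male", 30), "height")
  expect_error(ebm_allometric(70, 1.7, "m", 30), "male.*female")
  expect_error(ebm_allometric(70, 1.7, 1, 30), "integer sex codes")
  expect_error(ebm_allometric(70, 1.7, "male", -2), "age")
})

test_that("additive EBM reproduces the printed hand arithmetic and tracks the allometric form", {
  # -0.58 + 0.18*76.6 + 7.20*1.75 - 0.08*20
  expect_equal(ebm_additive(76.6, 1.75, "male", 20), 24.208, tolerance = 1e-12)
  # -0.26 + 0.16*70 + 5.63*1.65 - 0.06*44
  expect_equal(ebm_additive(70, 1.65, "female", 44), 17.5895, tolerance = 1e-12)

  grid <- expand.grid(
    mass = seq(50, 110, by = 5),
    height = seq(1.5, 1.95, by = 0.05),
    age = seq(18, 79, by = 5),
    sex = c("male", "female"),
    stringsAsFactors = FALSE
  )
  # keep anthropometrically plausible combinations (the study's BMI range)
  bmi <- grid$mass / grid$height^2
  grid <- grid[bmi >= 18.5 & bmi <= 40, ]
  allo <- ebm_allometric(grid$mass, grid$height, grid$sex, grid$age)
  addi <- ebm_additive(grid$mass, grid$height, grid$sex, grid$age)
  expect_gt(cor(addi, allo), 0.99)

  # within the bulk of a realistic cohort the approximation stays within
  # 10% of the allometric form
  co <- generate_cohort(cohort_spec(n = 4000), seed = 17)
  allo_c <- ebm_allometric(co$mass_kg, co$height_m, co$sex, co$age)
  addi_c <- ebm_additive(co$mass_kg, co$height_m, co$sex, co$age)
  expect_lt(max(abs(addi_c - allo_c) / allo_c), 0.10)
  expect_gt(cor(addi_c, allo_c), 0.99)
})

test_that("additive EBM warns rather than errors when the linear form turns negative", {
  expect_warning(v <- ebm_additive(0.5, 0.2, "male", 90), "non-positive")
  expect_lt(v, 0)
})

test_that("EBM workload matches hand arithmetic, is >= 2, and is strictly increasing", {
  expect_equal(workload_ebm(0, 0, 0), 2.0)
  # 2 + 5*(1.06 + 5.22*0.10) + 0.019*108
  expect_equal(workload_ebm(5, 0.10, 108), 11.962, tolerance = 1e-12)
  base <- workload_ebm(4, 0.1, 100)
  expect_gt(workload_ebm(4.1, 0.1, 100), base)
  expect_gt(workload_ebm(4, 0.12, 100), base)
  expect_gt(workload_ebm(4, 0.1, 101), base)
  expect_error(workload_ebm(-1, 0, 0), "speed")
  expect_error(workload_ebm(1, 11, 0), "percent")
})

test_that("Kokkinos workload matches hand arithmetic and is 1 MET at rest", {
  expect_equal(workload_kokkinos(0, 0.3), 1.0)
  # (129 * (0.17 + 0.79*0.11) + 3.5) / 3.5
  expect_equal(workload_kokkinos(129, 0.11), 10.46861, tolerance = 1e-6)
  expect_error(workload_kokkinos(-5, 0), "speed")
})

test_that("VO2peak prediction composes the audited pieces under both standards", {
  # reference subject at 1 MET workload: 11 x EBM vs 3.5 x mass agree
  # within the rounding of the constant
  ref_ebm <- ebm_allometric(76.6, 1.75, "male", 20)
  expect_gt(11 * ref_ebm / (3.5 * 76.6), 11 / 11.5)
  expect_lt(11 * ref_ebm / (3.5 * 76.6), 11 / 10.5)

  # mass standard is 3.5 x mass x Kokkinos WL by default
  got <- predict_vo2peak(70, 1.7, "female", 30, speed = 3, grade = 0.05,
                         standard = "mass", hrr = 90)
  wl <- workload_kokkinos(3 * 26.8224, 0.05)
  expect_equal(got, 3.5 * 70 * wl, tolerance = 1e-12)

  # frozen composition for the cohort-mean man: 11 x EBM x WL by direct
  # arithmetic
  ebm_o <- 84^0.63 * 1.78^0.53 * 1.16 * exp(-0.39 * 0.44^2)
  wl_o <- 2 + 5.4 * (1.06 + 5.22 * 0.11) + 0.019 * 112
  got <- predict_vo2peak(84, 1.78, "male", 44, speed = 5.4, grade = 0.11,
                         hrr = 112, standard = "ebm")
  expect_equal(got, 11 * ebm_o * wl_o, tolerance = 1e-12)
  expect_equal(round(got), 3392)
})

test_that("indexing divides by the requested scaler and MET display is definitional", {
  expect_equal(round(index_vo2peak(2747, mass = 78), 1), 35.2)
  expect_equal(index_vo2peak(3.5 * 82, mass = 82, met_display = TRUE), 1.0)
  ebm <- ebm_allometric(76.6, 1.75, "male", 20)
  expect_equal(index_vo2peak(11 * ebm, ebm = ebm, scaler = "ebm"), 11)
  expect_equal(index_vo2peak(11 * ebm, ebm = ebm, scaler = "ebm",
                             met_display = TRUE), 1.0)
  expect_equal(index_vo2peak(2747, mass = 78, scaler = "mass_0p7"),
               2747 / 78^0.7)
  expect_error(index_vo2peak(2747, mass = 78, scaler = "mass_0p7",
                             met_display = TRUE), "mass_0p7")
})

test_that("LBM and BCM relations are linear / power as published", {
  expect_equal(lbm_equivalent(1), 1.61)
  expect_equal(bcm_scale(1), 1.0)
  expect_equal(round(bcm_scale(23.6), 1), 33.4)
  x <- c(5, 12.5, 30)
  expect_equal(lbm_equivalent(2 * x), 2 * lbm_equivalent(x))
  expect_error(bcm_scale(-1), "ebm")
})

test_that("unit conversions use the exact factor and reproduce the printed MET rows", {
  expect_equal(convert_speed(1), 26.8224)
  expect_equal(convert_speed(convert_speed(5), from = "m_per_min", to = "mph"), 5)
  expect_equal(vo2_to_mets(3.5 * 70 * 8, 70), 8)
  expect_equal(round(relative_vo2_to_mets(35.6), 1), 10.2)
  expect_equal(round(relative_vo2_to_mets(29.9), 1), 8.5)
})

test_that("scaling constants are overridable and unknown keys are rejected", {
  k <- ebm_constants(mass_exp = 0.7, kokkinos = c(speed = 0.2, grade = 0.8, rest = 3.5))
  expect_equal(k$mass_exp, 0.7)
  expect_equal(unname(k$kokkinos["speed"]), 0.2)
  expect_error(ebm_constants(not_a_constant = 1), "Unknown scaling constant")
  expect_error(ebm_constants(additive_male = c(1, 2)), "length 4")

  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(male_factor = 1.2), cfg, auto_unbox = TRUE)
  expect_equal(ebm_constants(file = cfg)$male_factor, 1.2)
  # explicit overrides beat the file
  expect_equal(ebm_constants(male_factor = 1.3, file = cfg)$male_factor, 1.3)
  unlink(cfg)

  # overridden constants flow through the equations
  expect_equal(
    ebm_allometric(70, 1.7, "male", 40, constants = ebm_constants(male_factor = 1)),
    ebm_allometric(70, 1.7, "female", 40)
  )
})
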