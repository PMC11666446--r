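test_that("noiseless cohorts are identified exactly by the scaling refit", {
  co <- generate_cohort(cohort_spec(n = 1500, sigma = 0), seed = 41)
  fit <- fit_ebm_model(co, workload = "offset")
  expect_equal(fit$canonical$mass_exp, 0.63, tolerance = 1e-8)
  expect_equal(fit$canonical$height_exp, 0.53, tolerance = 1e-8)
  expect_equal(fit$canonical$male_factor, 1.16, tolerance = 1e-8)
  expect_equal(fit$canonical$age_coef, -0.39, tolerance = 1e-8)
  expect_lt(fit$sigma, 1e-10)
})

test_that("exponentiated log-scale predictions equal the multiplicative form", {
  co <- generate_cohort(cohort_spec(n = 400, sigma = 0), seed = 42)
  fit <- fit_ebm_model(co, workload = "offset")
  est <- setNames(coef(fit$model), names(coef(fit$model)))
  pred_log <- exp(fitted(fit$model))
  terms <- fit$retained$term
  mult <- exp(est[["(Intercept)"]])
  fage <- co$age / 100
  cols <- list(
    ln_mass = log(co$mass_kg), ln_height = log(co$height_m),
    male = as.numeric(co$sex == "male"),
    fage = fage, fage2 = fage^2, fage3 = fage^3
  )
  for (t in terms) mult <- mult * exp(est[[t]] * cols[[t]])
  expect_equal(unname(pred_log), unname(mult), tolerance = 1e-12)
})

test_that("backward elimination is deterministic and only removes terms above the threshold", {
  co <- generate_cohort(cohort_spec(n = 2000), seed = 43)
  f1 <- fit_ebm_model(co)
  f2 <- fit_ebm_model(co)
  expect_identical(f1$eliminated, f2$eliminated)
  expect_identical(f1$retained, f2$retained)
  if (nrow(f1$eliminated)) expect_true(all(f1$eliminated$p_exit > 0.05))
  expect_true(all(f1$retained$p.value <= 0.05))
  # elimination proceeds one term per iteration
  if (nrow(f1$eliminated)) {
    expect_identical(f1$eliminated$step, seq_len(nrow(f1$eliminated)))
  }
})

test_that("a genuine cubic-age signal is retained, not eliminated", {
  co <- generate_cohort(cohort_spec(n = 3000, sigma = 0.05), seed = 44)
  fage <- co$age / 100
  co$vo2peak_ml_min <- co$vo2peak_ml_min * exp(-1.5 * fage^3)
  fit <- fit_ebm_model(co, workload = "offset")
  expect_true("fage3" %in% fit$retained$term)
})

test_that("rank deficiency raises a diagnostic error naming the collinear term", {
  co <- small_cohort(n = 100, seed = 45)
  co$height_m <- 1.7 # constant: ln_height is collinear with the intercept
  expect_error(fit_ebm_model(co), "rank deficient.*ln_height")
})

test_that("parameter recovery is unbiased over seeded replicates of the default design", {
  est <- vapply(1:50, function(i) {
    co <- generate_cohort(cohort_spec(), seed = 500 + i)
    fit_ebm_model(co)$canonical$mass_exp
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.63), 2 * mc_se)
})

test_that("the workload equation is recovered exactly without noise and its terms can be restricted", {
  co <- generate_cohort(cohort_spec(n = 1200, sigma = 0), seed = 46)
  fit <- fit_workload_equation(co)
  expect_equal(unname(coef(fit)),
               c(2, 1.06, 5.22, 0.019), tolerance = 1e-8)

  # dropping HRR forces the speed terms upward in compensation
  fit_nohrr <- fit_workload_equation(co, terms = c("speed", "speed_grade"))
  expect_identical(unname(coef(fit_nohrr)["hrr"]), 0)
  expect_gt(coef(fit_nohrr)["speed"], coef(fit)["speed"])
})

test_that("the additive approximation identifies planar data exactly and fits synthetic strata well", {
  # points lying exactly on the printed planes
  grid <- expand.grid(mass = c(60, 75, 90, 105), height = c(1.55, 1.7, 1.85),
                      age = c(25, 45, 65))
  male_plane <- -0.58 + 0.18 * grid$mass + 7.20 * grid$height - 0.08 * grid$age
  female_plane <- -0.26 + 0.16 * grid$mass + 5.63 * grid$height - 0.06 * grid$age
  toy <- tibble::tibble(
    mass_kg = rep(grid$mass, 2),
    height_m = rep(grid$height, 2),
    age = rep(grid$age, 2),
    sex = rep(c("male", "female"), each = nrow(grid))
  )
  fit <- fit_additive_approximation(toy, ebm = c(male_plane, female_plane))
  cm <- fit$coefficients[fit$coefficients$sex == "male", ]
  cf <- fit$coefficients[fit$coefficients$sex == "female", ]
  expect_equal(unlist(cm[, -1], use.names = FALSE),
               c(-0.58, 0.18, 7.20, -0.08), tolerance = 1e-10)
  expect_equal(unlist(cf[, -1], use.names = FALSE),
               c(-0.26, 0.16, 5.63, -0.06), tolerance = 1e-10)

  # allometric EBM over a synthetic stratum: near-unity R2 and the
  # published sign pattern
  co <- small_cohort(n = 600, seed = 47)
  fit2 <- fit_additive_approximation(co)
  expect_true(all(fit2$r.squared >= 0.98))
  expect_true(all(fit2$coefficients$mass > 0))
  expect_true(all(fit2$coefficients$height > 0))
  expect_true(all(fit2$coefficients$age < 0))

  expect_error(
    fit_additive_approximation(toy[c(1, 2, 3, nrow(grid) + 1), ]),
    "Insufficient data"
  )
})

test_that("tidiers return the expected shapes", {
  co <- small_cohort(n = 400, seed = 48)
  f <- fit_ebm_model(co)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(f)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$r.squared >= 0 && gl$r.squared <= 1)

  w <- fit_workload_equation(co)
  expect_true("intercept" %in% tidy(w)$term)
  expect_identical(nrow(glance(w)), 1L)

  a <- fit_additive_approximation(co)
  expect_identical(nrow(glance(a)), 1L)
  expect_setequal(unique(tidy(a)$term), c("intercept", "mass", "height", "age"))
})
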