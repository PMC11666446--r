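# Shared fixtures, built in code.

# small healthy cohort for fast structural tests
small_cohort <- function(n = 200, seed = 11, ...) {
  generate_cohort(cohort_spec(n = n, ...), seed = seed)
}

# degenerate cohort: every subject performs the identical workload, so
# VO2peak is exactly proportional to EBM (sigma = 0)
constant_wl_cohort <- function(n = 100, seed = 21) {
  spec <- cohort_spec(
    n = n, sigma = 0,
    speed = list(male = list(mean = 5, sd = 0), female = list(mean = 5, sd = 0),
                 age_slope = 0, min = 0),
    grade = list(male = list(mean = 0.1, sd = 0), female = list(mean = 0.1, sd = 0),
                 min = 0, max = 0.4),
    hrr = list(male = list(mean = 100, sd = 0), female = list(mean = 100, sd = 0),
               age_slope = 0, min = 0)
  )
  generate_cohort(spec, seed = seed)
}

# brute-force oracles, independent of the package implementation
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_slope_origin <- function(x, y) sum(x * y) / sum(x * x)

oracle_cohens_d <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  (mean(a) - mean(b)) / sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
}
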