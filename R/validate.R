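# Input validation shared across the package. All checks are vectorised
# and name the offending argument so CSV readers and the command line can
# surface actionable messages.

normalize_sex <- function(sex, arg = "sex") {
  if (is.factor(sex)) sex <- as.character(sex)
  if (is.numeric(sex)) {
    abort(sprintf(
      "`%s` must be the strings \"male\"/\"female\"; integer sex codes are rejected to prevent silent miscoding.",
      arg
    ))
  }
  out <- tolower(trimws(as.character(sex)))
  bad <- !is.na(out) & !out %in% c("male", "female")
  if (any(bad)) {
    abort(sprintf(
      "`%s` contains invalid value(s): %s. Use \"male\" or \"female\".",
      arg, paste(unique(out[bad]), collapse = ", ")
    ))
  }
  if (anyNA(out)) abort(sprintf("`%s` contains missing values.", arg))
  out
}

check_numeric <- function(x, arg, positive = FALSE, nonnegative = FALSE,
                          finite = TRUE) {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", arg))
  if (anyNA(x)) abort(sprintf("`%s` contains missing values.", arg))
  if (finite && any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  if (positive && any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive.", arg))
  }
  if (nonnegative && any(x < 0)) {
    abort(sprintf("`%s` must be non-negative.", arg))
  }
  invisible(x)
}

check_grade <- function(grade, arg = "grade") {
  check_numeric(grade, arg, nonnegative = TRUE)
  if (any(grade > 1)) {
    abort(sprintf(
      "`%s` must be a fraction in [0, 1] (e.g. 0.11 for an 11%% incline). Values above 1 look like percent; divide by 100.",
      arg
    ))
  }
  invisible(grade)
}

# recycle scalar arguments against the longest input, erroring on
# incompatible lengths (base-R recycling is too permissive here)
recycle_args <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  out <- lapply(names(args), function(k) {
    x <- args[[k]]
    if (length(x) == n) return(x)
    if (length(x) == 1L) return(rep(x, n))
    abort(sprintf(
      "`%s` has length %d; expected 1 or %d.", k, length(x), n
    ))
  })
  names(out) <- names(args)
  out
}
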