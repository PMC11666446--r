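#' Tidiers for fitted objects
#'
#' Broom-style [generics::tidy()] and [generics::glance()] methods for
#' the package's fit classes.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble: `tidy()` one row per term, `glance()` one row per
#'   fit.
#' @name ebmscale-tidiers
NULL

#' @rdname ebmscale-tidiers
#' @method tidy ebm_fit
#' @export
tidy.ebm_fit <- function(x, ...) x$retained

#' @rdname ebmscale-tidiers
#' @method glance ebm_fit
#' @export
glance.ebm_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared,
    sigma = x$sigma,
    n = x$n,
    n_retained = nrow(x$retained),
    n_eliminated = nrow(x$eliminated),
    p_sex_interaction = x$sex_interaction$p
  )
}

#' @rdname ebmscale-tidiers
#' @method tidy wl_fit
#' @export
tidy.wl_fit <- function(x, ...) {
  ct <- quiet_summary(x$model)$coefficients
  tibble::tibble(
    term = sub("^\\(Intercept\\)$", "intercept", rownames(ct)),
    estimate = ct[, "Estimate"],
    std.error = ct[, "Std. Error"],
    statistic = ct[, "t value"],
    p.value = ct[, "Pr(>|t|)"]
  )
}

#' @rdname ebmscale-tidiers
#' @method glance wl_fit
#' @export
glance.wl_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared,
    sigma = x$sigma,
    n = x$n,
    met_constant = x$met_constant,
    n_eliminated = nrow(x$eliminated)
  )
}

#' @rdname ebmscale-tidiers
#' @method tidy ebm_additive_fit
#' @export
tidy.ebm_additive_fit <- function(x, ...) {
  tidyr::pivot_longer(x$coefficients, -"sex", names_to = "term",
                      values_to = "estimate")
}

#' @rdname ebmscale-tidiers
#' @method glance ebm_additive_fit
#' @export
glance.ebm_additive_fit <- function(x, ...) {
  tibble::tibble(
    r.squared_male = unname(x$r.squared["male"]),
    r.squared_female = unname(x$r.squared["female"]),
    valid = x$valid
  )
}
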