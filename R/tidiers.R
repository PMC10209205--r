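#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn fit_stepping One row per gain: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy stepping_fit
#' @export
tidy.stepping_fit <- function(x, ...) {
  tv <- x$gains / x$se
  tibble::tibble(
    term = names(x$gains),
    estimate = unname(x$gains),
    std.error = unname(x$se),
    statistic = unname(tv),
    p.value = unname(2 * pt(abs(tv), x$df_residual, lower.tail = FALSE)))
}

#' @describeIn fit_stepping One-row model summary: `r.squared`, `sigma`,
#'   `n_strides`, `direction`.
#' @method glance stepping_fit
#' @export
glance.stepping_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$sigma,
                 n_strides = x$n_strides, direction = x$direction)
}

#' @describeIn fit_compensation One row per strategy gain.
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy compensation_fit
#' @export
tidy.compensation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ankle", "trunk"),
    estimate = c(x$ankle_gain, x$trunk_gain),
    std.error = unname(x$se),
    statistic = unname(x$t_value),
    p.value = unname(x$p_value))
}

#' @describeIn fit_compensation One-row model summary.
#' @method glance compensation_fit
#' @export
glance.compensation_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_strides = x$n_strides)
}

#' @describeIn compute_lde One-row summary of the divergence fit.
#' @param x A fitted object.
#' @param ... Unused.
#' @method glance lde_fit
#' @export
glance.lde_fit <- function(x, ...) {
  tibble::tibble(lde = x$lde, n_points = x$n_points, dim = x$dim,
                 delay = x$delay,
                 fit_lo = x$fit_range[1], fit_hi = x$fit_range[2])
}
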