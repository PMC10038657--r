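#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Bhattacharyya surface into long form
#'
#' @param x A `bc_surface` from [scan_scaling_grid()].
#' @param ... Unused.
#' @return A tibble with one row per `(mu, g)` grid point and columns
#'   `mu`, `g`, `bc`.
#' @export
tidy.bc_surface <- function(x, ...) {
  tidyr::expand_grid(mu = x$mu_grid, g = x$g_grid) |>
    dplyr::mutate(bc = as.vector(t(x$bc)))
}

#' @rdname tidy.bc_surface
#' @return For `glance()`: a one-row tibble with `mu_star`, `g_star`,
#'   `bc_max`, `ridge_ratio`.
#' @export
glance.bc_surface <- function(x, ...) {
  tibble::tibble(mu_star = x$argmax$mu_star, g_star = x$argmax$g_star,
                 bc_max = x$argmax$bc_max, ridge_ratio = x$ridge_ratio)
}

#' Tidy methods for test results and estimates
#'
#' `f3_result` and `pulse_time_estimate` are already one-row tibbles, so
#' `tidy()` and `glance()` return them unchanged (dropping the class);
#' for `perm_test_result`, `tidy()` returns the null correlations and
#' `glance()` the observed correlation and p-value.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.f3_result <- function(x, ...) tibble::as_tibble(unclass_row(x))

#' @rdname tidy.f3_result
#' @export
glance.f3_result <- function(x, ...) tidy.f3_result(x)

#' @rdname tidy.f3_result
#' @export
tidy.pulse_time_estimate <- function(x, ...) tibble::as_tibble(unclass_row(x))

#' @rdname tidy.f3_result
#' @export
glance.pulse_time_estimate <- function(x, ...) tidy.pulse_time_estimate(x)

#' @rdname tidy.f3_result
#' @export
tidy.perm_test_result <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null_r), r_null = x$null_r)
}

#' @rdname tidy.f3_result
#' @export
glance.perm_test_result <- function(x, ...) {
  tibble::tibble(r_obs = x$r_obs, p = x$p, n_perm = x$n_perm,
                 alternative = x$alternative)
}

#' @rdname tidy.f3_result
#' @export
tidy.power_result <- function(x, ...) x$summary

unclass_row <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
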