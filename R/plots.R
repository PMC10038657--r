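#' Plot a Bhattacharyya calibration surface
#'
#' Heat map of the overlap coefficient over the mutation-rate and
#' generation-time grid, with the best-matching `mu/g` ray drawn as a
#' dashed line and the argmax marked.
#'
#' @param object A `bc_surface` from [scan_scaling_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bc_surface <- function(object, ...) {
  df <- tidy(object)
  ridge <- tibble::tibble(g = range(object$g_grid)) |>
    dplyr::mutate(mu = .data$g * object$ridge_ratio)
  ggplot2::ggplot(df, ggplot2::aes(.data$mu, .data$g, fill = .data$bc)) +
    ggplot2::geom_raster() +
    ggplot2::geom_line(data = ridge, ggplot2::aes(.data$mu, .data$g),
                       inherit.aes = FALSE, linetype = "dashed") +
    ggplot2::annotate("point", x = object$argmax$mu_star, y = object$argmax$g_star) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "BC") +
    ggplot2::labs(x = "mutation rate (per site per generation)",
                  y = "generation time (years)")
}

#' Plot a rescaled migration density against the historical record
#'
#' @param density Density tibble from [migration_density_in_years()].
#' @param record Historical record tibble.
#' @return A ggplot with the normalized record as bars and the rescaled
#'   migration density as a step line.
#' @export
plot_calibration <- function(density, record) {
  rec <- normalize_record(record)
  ggplot2::ggplot(rec, ggplot2::aes(x = (.data$start_year + .data$end_year) / 2,
                                    y = .data$weight)) +
    ggplot2::geom_col(fill = "pink", width = rec$end_year[1] - rec$start_year[1]) +
    ggplot2::geom_step(data = density,
                       ggplot2::aes(x = .data$start_year, y = .data$weight),
                       direction = "hv") +
    ggplot2::labs(x = "calendar year", y = "normalized weight")
}

#' Plot called ancestry tracts across individuals
#'
#' Heterozygous tracts in purple, homozygous-specialist tracts in red,
#' one row per individual per chromosome facet.
#'
#' @param tracts Tract tibble from [call_tracts()].
#' @return A ggplot.
#' @export
plot_tracts <- function(tracts) {
  ggplot2::ggplot(tracts,
                  ggplot2::aes(x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
                               y = .data$individual, yend = .data$individual,
                               colour = .data$dosage_class)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(heterozygous = "purple",
                                            homozygous = "red")) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = NULL)
}

#' Plot a power-experiment summary
#'
#' @param object A `power_result` from [run_power_experiment()].
#' @param ... Unused.
#' @return A ggplot of sensitivity and precision against tract length.
#' @export
autoplot.power_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary, c("sensitivity", "precision"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$tract_length_bp / 1e6, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "implanted tract length (Mb)", y = "fraction of bp",
                  colour = NULL)
}

#' Plot a migration trajectory in calendar time
#'
#' @param traj Migration trajectory tibble.
#' @param s A [scaling_factor()].
#' @return A ggplot of the migration density and cumulative migration
#'   against years before present.
#' @export
plot_migration_trajectory <- function(traj, s) {
  df <- traj[is.finite(traj$right_time_boundary), ]
  df <- tibble::tibble(
    years_bp = scale_to_years(df$left_time_boundary, s),
    m = df$m / max(df$m), M = df$M)
  df <- tidyr::pivot_longer(df, c("m", "M"), names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(.data$years_bp, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "years before present",
                  y = "migration (density rescaled to max 1; cumulative M)",
                  colour = NULL)
}
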