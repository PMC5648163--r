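#' @export
autoplot.tooth_section <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$pixels)),
                           col = seq_len(ncol(object$pixels)))
  df$grey <- as.vector(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$grey)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "grey") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, %g days", object$specimen_id,
                                  object$age_days),
                  x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flattened_enamel <- function(object, ...) {
  df <- tidyr::expand_grid(x = object$arc_mm,
                           depth = object$depth_rel)
  df$density <- as.vector(t(object$densities))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$depth,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(rho ~ (g / cm^3)),
                                  na.value = "grey90") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "EDJ distance (mm)", y = "relative depth",
                  title = sprintf("%s, %g days (flattened)",
                                  object$specimen_id, object$age_days)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.growth_curve_fit <- function(object, ...) {
  p <- object$params
  tt <- seq(min(object$residuals$age_days) - 30,
            max(object$residuals$age_days) + 30, length.out = 200)
  curve_df <- tibble::tibble(age_days = tt,
                             position_mm = extension_length(tt, p))
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(.data$age_days, .data$position_mm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve_df, color = "steelblue") +
    ggplot2::labs(x = "age (days)", y = "position along EDJ (mm)",
                  title = sprintf("%s growth curve", object$curve_kind)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trajectory_posterior <- function(object, ...) {
  stopifnot(isTRUE(object$usable))
  s <- object$samples
  df <- tibble::tibble(
    time = rep(object$times, each = nrow(s)),
    density = as.vector(s),
    sample = rep(seq_len(nrow(s)), ncol(s))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$density,
                                   group = .data$sample)) +
    ggplot2::geom_line(alpha = 0.15, color = "steelblue") +
    ggplot2::labs(x = "size-modeled age (days)",
                  y = expression(rho ~ (g / cm^3)),
                  title = "Retained monotone trajectories") +
    ggplot2::theme_minimal()
}

#' Plot one time slice of a mineralization-rate field
#'
#' @param rates A `rate_field`.
#' @param day Which day (index into the rate time axis).
#' @return A ggplot raster of deposition rate over the standardized grid.
#' @export
plot_rate_slice <- function(rates, day) {
  stopifnot(inherits(rates, "rate_field"))
  df <- tibble::tibble(
    x_bin = rates$locations[, 1], depth_bin = rates$locations[, 2],
    rate = rates$rates[, day]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x_bin, .data$depth_bin,
                                   fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno",
                                  name = "% / day") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "EDJ distance bin", y = "depth bin",
                  title = sprintf("Deposition rate, day %0.1f",
                                  rates$days[day])) +
    ggplot2::theme_minimal()
}
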