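#' Plot pole and chromosome trajectories
#'
#' @param traj Trajectory tibble (shared schema), possibly multi-cell.
#' @return A ggplot: D_P-P and D_C-C versus time, one line set per cell.
#' @export
plot_trajectories <- function(traj) {
  stopifnot(is.data.frame(traj))
  long <- traj |>
    tidyr::pivot_longer(cols = c("d_pp_um", "d_cc_um"),
                        names_to = "quantity", values_to = "distance_um") |>
    dplyr::mutate(quantity = dplyr::recode(.data$quantity,
                                           d_pp_um = "pole-to-pole",
                                           d_cc_um = "chromosome-to-chromosome"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$distance_um,
                                     colour = .data$quantity,
                                     group = interaction(.data$cell_id, .data$quantity))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time since anaphase onset (s)", y = "distance (µm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$d_um), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "time since anaphase onset (s)", y = "D_P-P (µm)",
                  subtitle = sprintf("FLPP = %.2f µm, ERPP = %.2f µm/min",
                                     object$flpp, object$erpp)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.exp_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$d_um), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "time since anaphase onset (s)", y = "D_C-C (µm)",
                  subtitle = sprintf("FLCC = %.2f µm, SRCC = %.2f µm/min",
                                     object$flcc, object$srcc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scaling_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$size, y = .data$quantity)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cell size (µm)", y = "quantity",
                  subtitle = sprintf("%s slope = %.3f ± %.3f",
                                     object$convention, object$slope, object$slope_sd)) +
    ggplot2::theme_minimal()
  if (object$convention == "loglog") {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::geom_line(data = tibble::tibble(
        size = object$data$size,
        quantity = exp(object$intercept) * object$data$size^object$slope),
        colour = "steelblue")
  } else {
    p <- p + ggplot2::geom_abline(intercept = object$intercept,
                                  slope = object$slope, colour = "steelblue")
  }
  p
}

#' @export
autoplot.piecewise_fit <- function(object, ...) {
  grid <- tibble::tibble(size = seq(min(object$data$size), max(object$data$size),
                                    length.out = 200))
  grid$rate <- object$plateau + object$slope_below * pmin(grid$size - object$breakpoint, 0)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$size, y = .data$rate)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$breakpoint, linetype = 2) +
    ggplot2::labs(x = "cell size (µm)", y = "elongation rate (µm/min)",
                  subtitle = sprintf("transition at %.1f µm", object$breakpoint)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(frame = seq_len(nrow(object$intensity)) - 1L,
                           px = seq_len(ncol(object$intensity)) - 1L)
  df$intensity <- as.vector(t(object$intensity))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px * object$pixel_um,
                                   y = .data$frame * object$frame_s,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position along spindle axis (µm)", y = "time (s)",
                  fill = object$channel) +
    ggplot2::theme_minimal()
}
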