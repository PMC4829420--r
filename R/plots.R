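# ggplot2 autoplot() methods for the package's result types.

#' Plot trajectories as position versus time
#'
#' @param object A `trajectory_set` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.trajectory_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$position_um,
                                       group = .data$particle_id,
                                       colour = factor(.data$particle_id))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "time (s)", y = "position along DNA (µm)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_s, .data$msd_um2)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag τ (s)", y = "MSD (µm²)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.diffusion_fit <- function(object, ...) {
  curve <- object$curve
  win <- seq(object$fit_window[1], object$fit_window[2])
  line <- tibble(lag_s = curve$lag_s,
                 fit = object$offset_um2 +
                   2 * object$D_um2_per_s * curve$lag_s)
  ggplot2::ggplot(curve, ggplot2::aes(.data$lag_s, .data$msd_um2)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::geom_point(data = curve[win, ], colour = "black") +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$fit),
                       colour = "red") +
    ggplot2::labs(x = "lag τ (s)", y = "MSD (µm²)",
                  subtitle = sprintf("D = %.3g µm²/s", object$D_um2_per_s))
}

#' @exportS3Method ggplot2::autoplot
autoplot.image_stack <- function(object, ...) {
  km <- as_kymograph(object)
  df <- tibble(frame = rep(seq_len(nrow(km)), times = ncol(km)),
               pixel = rep(seq_len(ncol(km)), each = nrow(km)),
               counts = as.vector(km))
  ggplot2::ggplot(df, ggplot2::aes(.data$pixel, .data$frame,
                                   fill = .data$counts)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position (px)", y = "frame", fill = "counts")
}

#' @exportS3Method ggplot2::autoplot
autoplot.mc_search_result <- function(object, ...) {
  ggplot2::ggplot(object$times, ggplot2::aes(.data$time_s)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$median_s, colour = "red") +
    ggplot2::labs(x = "search time (s)", y = "replicates")
}

#' @exportS3Method ggplot2::autoplot
autoplot.first_order_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time (s)", y = "signal")
}

#' @exportS3Method ggplot2::autoplot
autoplot.competition_fit <- function(object, ...) {
  df <- object$data[object$data$concentration > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$concentration,
                                   .data$fraction_bound)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "competitor concentration", y = "fraction bound")
}
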