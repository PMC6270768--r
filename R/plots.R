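# ggplot2 output for the main result types.

#' Plot per-atom fluctuations
#'
#' @param rmsf Tibble from [atomic_fluctuations()] or [mode_rmsf()].
#' @return A ggplot.
#' @export
plot_rmsf <- function(rmsf) {
  ycol <- if ("rmsf" %in% names(rmsf)) "rmsf" else "amplitude"
  ggplot2::ggplot(rmsf, ggplot2::aes(x = .data$atom, y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "core atom", y = "fluctuation (Å)") +
    ggplot2::theme_minimal()
}

#' Plot RMSD series against references
#'
#' @param series Tibble from [rmsd_series()].
#' @param x `"frame"` or `"time_ps"`.
#' @return A ggplot.
#' @export
plot_rmsd_series <- function(series, x = c("frame", "time_ps")) {
  x <- match.arg(x)
  ggplot2::ggplot(series, ggplot2::aes(x = .data[[x]], y = .data$rmsd,
                                       colour = .data$reference)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.overlap_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode_b, y = .data$mode_a,
                                   fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = c("blue", "green", "red"),
                                  limits = c(0, 1)) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(object))) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(object))) +
    ggplot2::labs(x = "system B mode", y = "system A mode",
                  fill = "|inner product|") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.asp_cast <- function(object, ...) {
  ggplot2::ggplot(object$activation_log,
                  ggplot2::aes(x = .data$event, y = .data$accumulated_force)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "activation event",
                  y = "accumulated force on activated particle (kcal/mol/Å)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.eigen_system <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mode", y = "variance fraction") +
    ggplot2::theme_minimal()
}

#' Plot projections of leading modes against time
#'
#' Oscillating projections indicate thermal modes; a monotone projection
#' marks a pressurisation drift mode.
#'
#' @param e An `eigen_system`.
#' @param n Number of leading modes (default 4).
#' @return A ggplot.
#' @export
plot_projections <- function(e, n = 4) {
  n <- min(n, ncol(e$projections))
  df <- purrr::map(seq_len(n), function(m) {
    tibble(time_ps = e$times, mode = factor(m),
           projection = e$projections[, m])
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ps, y = .data$projection,
                                   colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "projection (Å)") +
    ggplot2::theme_minimal()
}

#' Plot a latent-force map as a 2D projection
#'
#' @param map Tibble from [latent_force_map()].
#' @param plane Which coordinate plane to project onto (default `"xy"`).
#' @return A ggplot.
#' @export
plot_latent_force_map <- function(map, plane = c("xy", "xz", "yz")) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  ggplot2::ggplot(map, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                    colour = .data$force)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::labs(colour = "force\n(kcal/mol/Å)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
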