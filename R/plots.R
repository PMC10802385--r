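#' Plot the ensemble pairing fraction over time
#'
#' @param x A `pairing_fraction` tibble (see [pairing_fraction()]), or a
#'   named list of them (one line per scenario, e.g. a velocity sweep).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_pairing_fraction <- function(x, ...) {
  if (!inherits(x, "data.frame") && is.list(x)) {
    x <- dplyr::bind_rows(x, .id = "scenario")
    p <- ggplot2::ggplot(x, ggplot2::aes(.data$time_h, 100 * .data$fraction,
                                         colour = .data$scenario))
  } else {
    p <- ggplot2::ggplot(x, ggplot2::aes(.data$time_h, 100 * .data$fraction))
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (h)", y = "homologs paired (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_pairing_fraction
#' @param object A `pairing_fraction`.
#' @export
autoplot.pairing_fraction <- function(object, ...) plot_pairing_fraction(object, ...)

#' Plot distance curves indexed by initial distance or size
#'
#' Mean +/- SD homolog (or matched non-homolog control) distance per pair
#' rank at the reported display times; the 400 nm pairing band is shaded.
#'
#' @param x A `distance_curves` tibble ([distance_curves()]) or a
#'   `control_match` (its `curves` element is drawn).
#' @param threshold Pairing threshold drawn as a shaded band (um).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_distance_curves <- function(x, threshold = 0.4, ...) {
  if (inherits(x, "control_match")) x <- x$curves
  ggplot2::ggplot(x, ggplot2::aes(.data$rank, .data$mean_um,
                                  colour = factor(.data$time_h))) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0,
                      ymax = threshold, alpha = 0.15, fill = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$mean_um - .data$sd_um, 0),
      ymax = .data$mean_um + .data$sd_um),
      position = ggplot2::position_dodge(width = 0.5), size = 0.25) +
    ggplot2::labs(x = "homolog pair (ranked)", y = "distance (µm)",
                  colour = "time (h)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_distance_curves
#' @param object A `distance_curves`.
#' @export
autoplot.distance_curves <- function(object, ...) plot_distance_curves(object, ...)

#' Plot a nucleus snapshot
#'
#' Positions of all chromosomes of one realization at one sample time inside
#' the nuclear envelope; homolog pairs share a colour and captured pairs are
#' drawn solid.
#'
#' @param traj A `pairing_trajectory`.
#' @param time_h Displayed time to draw (nearest sample is used).
#' @param realization Which realization to draw.
#' @param nucleus_radius Envelope radius (um).
#' @return A ggplot.
#' @export
plot_nucleus <- function(traj, time_h = 3, realization = 1,
                         nucleus_radius = 3.25) {
  tt <- sort(unique(traj$time_h))
  pick <- tt[which.min(abs(tt - time_h))]
  snap <- traj[traj$time_h == pick & traj$realization == realization, ]
  ch <- traj_chromosomes(traj)
  snap <- dplyr::inner_join(snap, ch[, c("chrom_id", "pair_id")],
                            by = "chrom_id")
  th <- seq(0, 2 * pi, length.out = 181)
  ring <- tibble::tibble(x = nucleus_radius * cos(th),
                         y = nucleus_radius * sin(th))
  ggplot2::ggplot(snap, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_path(data = ring, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$pair_id),
                                     shape = .data$paired), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  colour = "pair", shape = "paired",
                  title = sprintf("t = %.1f h", pick)) +
    ggplot2::theme_minimal()
}
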