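#' Plot axon trajectories
#'
#' One path per axon over the 2D cord, with barriers drawn in red and
#' pioneer axons in black, mirroring the figures this model is usually
#' inspected with.
#'
#' @param trajectories A [grow_axons()] result.
#' @param environment Environment to draw barriers from (defaults to the
#'   one stored on the trajectories).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, environment = NULL) {
  env <- environment %||% attr(trajectories, "environment", exact = TRUE)
  pop <- attr(trajectories, "population", exact = TRUE)
  df <- dplyr::mutate(tibble::as_tibble(trajectories),
                      axon_id = paste(.data$neuron_id, .data$axon))
  if (!is.null(pop))
    df <- dplyr::left_join(df, dplyr::select(pop, "id", "pioneer"),
                           by = c(neuron_id = "id"))
  else df$pioneer <- FALSE
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        group = .data$axon_id)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$type,
                                    linetype = .data$axon,
                                    alpha = .data$pioneer), linewidth = 0.3) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.6),
                                guide = "none") +
    ggplot2::labs(x = "rostro-caudal x (um)", y = "dorso-ventral y (um)") +
    ggplot2::theme_minimal()
  if (!is.null(env)) {
    segs <- lapply(seq_len(nrow(env$barriers)), function(i) {
      b <- env$barriers[i, ]
      g <- env$gaps[[i]]
      xs <- sort(c(b$x_start, b$x_end, g))
      blocked <- matrix(xs, ncol = 2, byrow = TRUE)
      data.frame(x = blocked[, 1], xend = blocked[, 2], y = b$y_level)
    })
    segs <- do.call(rbind, segs)
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$y),
      inherit.aes = FALSE, colour = "red", linewidth = 0.6)
  }
  p
}

#' @rdname plot_trajectories
#' @param object,... autoplot interface.
#' @export
autoplot.fascicle_trajectories <- function(object, ...) {
  plot_trajectories(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dorso-ventral distribution
#'
#' @param dv A [dv_distribution()] tibble.
#' @return A ggplot object.
#' @export
plot_dv_distribution <- function(dv) {
  ggplot2::ggplot(dv, ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "dorso-ventral y (um)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a spike raster
#'
#' @param raster A `fascicle_raster`.
#' @return A ggplot object.
#' @export
plot_raster <- function(raster) {
  ggplot2::ggplot(raster, ggplot2::aes(.data$t, .data$neuron,
                                       colour = .data$type)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::facet_grid(side ~ ., scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' @rdname plot_raster
#' @param object,... autoplot interface.
#' @export
autoplot.fascicle_raster <- function(object, ...) plot_raster(object)
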