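# Diagnostic figures (ggplot2). These visualize single objects; benchmark
# figures are left to the user's own plotting over the tidy record tables.

#' Plot a fitted (or ground-truth) optogenetic receptive field
#'
#' Rasterizes one neuron's ORF on a regular grid around its centroid, with
#' the basis centers overlaid.
#'
#' @param object An `nbfr_fit` or `orf_population`.
#' @param neuron_id Which neuron to draw.
#' @param radius_um Half-width of the plotted window (default 40 um).
#' @param grid_um Raster spacing (default 1 um).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_orf <- function(object, neuron_id, radius_um = 40, grid_um = 1, ...) {
  cent <- orf_centroids(object)
  i <- match(neuron_id, cent$neuron_id)
  if (is.na(i)) abort("Unknown `neuron_id`.")
  gx <- seq(cent$x_um[i] - radius_um, cent$x_um[i] + radius_um, by = grid_um)
  gy <- seq(cent$y_um[i] - radius_um, cent$y_um[i] + radius_um, by = grid_um)
  pts <- cbind(rep(gx, length(gy)), rep(gy, each = length(gx)))
  b <- orf_bases(object)
  b <- b[b$neuron_id == neuron_id, , drop = FALSE]
  val <- if (nrow(b) == 0L) rep(0, nrow(pts)) else {
    d2 <- pairwise_sq_dist(pts, cbind(b$center_x, b$center_y))
    drop(exp(-sweep_width(d2, b$width, attr(orf_bases(object), "q")) / 2) %*% b$weight)
  }
  df <- tibble::tibble(x_um = pts[, 1L], y_um = pts[, 2L], response = val)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um, fill = .data$response)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = b, ggplot2::aes(.data$center_x, .data$center_y),
                        inherit.aes = FALSE, shape = 4, colour = "white") +
    ggplot2::annotate("point", cent$x_um[i], cent$y_um[i], shape = 21,
                      size = 3, colour = "white", fill = NA) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "evoked\nresponse",
                  title = sprintf("ORF, neuron %s", neuron_id))
}

#' @rdname plot_orf
#' @param x An `nbfr_fit`.
#' @export
autoplot.nbfr_fit <- function(object, neuron_id = NULL, ...) {
  if (is.null(neuron_id)) {
    neuron_id <- object$neurons$neuron_id[which.max(object$neurons$amplitude)]
  }
  plot_orf(object, neuron_id, ...)
}

#' Plot an optimization result: hologram paths and objective trace
#'
#' @param object A `stim_optimization`.
#' @param ... Unused.
#' @return A ggplot object (two panels via facetting).
#' @export
autoplot.stim_optimization <- function(object, ...) {
  paths <- purrr::imap(object$trajectories, function(m, j) {
    tibble::tibble(target = j, step = seq_len(nrow(m)),
                   x_um = m[, 1L], y_um = m[, 2L])
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(paths, ggplot2::aes(.data$x_um, .data$y_um,
                                      group = .data$target)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$step)) +
    ggplot2::geom_point(data = object$init,
                        ggplot2::aes(.data$x_um, .data$y_um),
                        inherit.aes = FALSE, shape = 21, size = 3) +
    ggplot2::geom_point(data = object$pattern,
                        ggplot2::aes(.data$x_um, .data$y_um),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "iteration",
                  title = sprintf("Hologram repositioning (objective %.3f → %.3f)",
                                  object$objective_init, object$objective))
}

#' Plot a PPSF radial profile
#'
#' @param object A `ppsf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppsf <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(.data$radius_um, .data$norm_response)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "distance from centroid (µm)",
                  y = "normalized response", size = "records",
                  title = "Physiological point spread function")
  if (!is.na(object$hwhm_um)) {
    p <- p + ggplot2::geom_vline(xintercept = object$hwhm_um, linetype = 3) +
      ggplot2::annotate("text", x = object$hwhm_um, y = 0.95, hjust = -0.1,
                        label = sprintf("HWHM %.1f µm", object$hwhm_um))
  }
  p
}
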