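# broom-style tidiers for the package's fitted objects.

#' Tidy an NBFR population fit
#'
#' @param x An `nbfr_fit`.
#' @param ... Unused.
#' @return One row per basis function: `neuron_id`, `site_id`, `center_x`,
#'   `center_y`, `weight`.
#' @export
tidy.nbfr_fit <- function(x, ...) {
  x$bases
}

#' @rdname tidy.nbfr_fit
#' @export
glance.nbfr_fit <- function(x, ...) {
  tibble::tibble(
    n_neurons = nrow(x$neurons),
    n_excitable = sum(x$neurons$excitable),
    n_bases = nrow(x$bases),
    median_bases_per_neuron = stats::median(x$neurons$n_bases),
    median_noise_sd = stats::median(x$neurons$noise_sd, na.rm = TRUE),
    length_scale = x$params$length_scale,
    q = x$params$q,
    inclusion_radius = x$params$inclusion_radius
  )
}

#' Tidy a stimulus-optimization result
#'
#' @param x A `stim_optimization`.
#' @param ... Unused.
#' @return One row per hologram: initial and optimized coordinates,
#'   displacement, iterations and convergence flag.
#' @export
tidy.stim_optimization <- function(x, ...) {
  tibble::tibble(
    neuron_id = x$pattern$neuron_id,
    init_x = x$init$x_um, init_y = x$init$y_um,
    x_um = x$pattern$x_um, y_um = x$pattern$y_um,
    displacement_um = sqrt((x$pattern$x_um - x$init$x_um)^2 +
                             (x$pattern$y_um - x$init$y_um)^2),
    objective_gain = vapply(x$traces, function(tr) tr[length(tr)] - tr[1L], 1.0),
    iterations = vapply(x$traces, length, 1L) - 1L,
    converged = x$converged
  )
}

#' @rdname tidy.stim_optimization
#' @export
glance.stim_optimization <- function(x, ...) {
  tibble::tibble(
    n_holograms = nrow(x$pattern),
    objective_init = x$objective_init,
    objective = x$objective,
    objective_gain = x$objective - x$objective_init,
    mean_displacement_um = mean(sqrt((x$pattern$x_um - x$init$x_um)^2 +
                                       (x$pattern$y_um - x$init$y_um)^2)),
    all_converged = all(x$converged)
  )
}

#' Tidy a PPSF estimate
#'
#' @param x A `ppsf`.
#' @param ... Unused.
#' @return The radial profile tibble.
#' @export
tidy.ppsf <- function(x, ...) {
  x$profile
}

#' @rdname tidy.ppsf
#' @export
glance.ppsf <- function(x, ...) {
  tibble::tibble(
    hwhm_um = x$hwhm_um,
    n_bins = nrow(x$profile),
    bin_width = x$bin_width,
    peak_response = max(x$profile$mean_response),
    n_records = sum(x$profile$n)
  )
}

#' Tidy a ground-truth population
#'
#' @param x An `orf_population`.
#' @param ... Unused.
#' @return One row per ground-truth ORF component.
#' @export
tidy.orf_population <- function(x, ...) {
  x$bases
}
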