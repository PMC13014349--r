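#' Super-Gaussian radial basis function
#'
#' Evaluates \eqn{\phi(x) = \exp(-\lVert c - x \rVert^q / (2\ell^q))}, the
#' radial basis used both to model optogenetic receptive fields (ORFs) and to
#' generate ground-truth ORFs in simulation. With `q = 2` this is the standard
#' Gaussian radial basis; with `q > 2` it is a "super-Gaussian" with a flatter
#' top and sharper falloff, which mimics the compact spatial profile of
#' soma-targeted photoexcitation.
#'
#' @param center Basis-function center: a length-2 `(x_um, y_um)` vector or an
#'   n x 2 matrix of centers (microns).
#' @param query Query point(s), same shapes accepted as `center`. When both are
#'   matrices they are paired row-wise (recycled if one has a single row).
#' @param length_scale Length scale \eqn{\ell} in microns; must be positive.
#' @param q Exponent (unitless); must be `>= 2`.
#' @return A numeric vector of basis values in `(0, 1]`; exactly 1 where the
#'   query coincides with the center.
#' @examples
#' basis_value(c(0, 0), c(6, 0), length_scale = 6, q = 2) # exp(-1/2)
#' @export
basis_value <- function(center, query, length_scale, q = 2) {
  check_basis_params(length_scale, q)
  center <- as_pattern_matrix(center)
  query <- as_pattern_matrix(query)
  n <- max(nrow(center), nrow(query))
  if (nrow(center) == 1L) center <- center[rep(1L, n), , drop = FALSE]
  if (nrow(query) == 1L) query <- query[rep(1L, n), , drop = FALSE]
  if (nrow(center) != nrow(query)) {
    abort("`center` and `query` must have compatible numbers of rows.")
  }
  d <- sqrt(rowSums((center - query)^2))
  exp(-d^q / (2 * length_scale^q))
}

check_basis_params <- function(length_scale, q) {
  if (!is.numeric(length_scale) || any(length_scale <= 0)) {
    abort("`length_scale` must be a positive number of microns.")
  }
  if (!is.numeric(q) || any(q < 2)) {
    abort("Basis exponent `q` must be >= 2.")
  }
  invisible(TRUE)
}

# phi evaluated from squared distances (vectorized hot path).
basis_value_sq <- function(d2, length_scale, q) {
  exp(-d2^(q / 2) / (2 * length_scale^q))
}

#' Assemble per-neuron basis sets from retained stimulation sites
#'
#' The NBFR model is "adaptive": each neuron's basis functions sit at exactly
#' those retained stimulation sites that lie within `inclusion_radius` of the
#' neuron's centroid, so the basis set is determined by the experiment's
#' stimulation geometry rather than fixed in advance. A site may serve in many
#' neurons' basis sets; a neuron with no site nearby has an empty basis set and
#' is unmappable.
#'
#' @param centroids Tibble with columns `neuron_id`, `x_um`, `y_um`.
#' @param sites Tibble of stimulation sites with columns `site_id`, `x_um`,
#'   `y_um` (e.g. the retained sites of [remove_redundant_sites()]).
#' @param length_scale,q Basis parameters shared by all neurons (microns /
#'   unitless). Defaults: 6 um and 2.
#' @param inclusion_radius Distance `d` (microns) within which a site joins a
#'   neuron's basis set. Default 30 um.
#' @return A tibble with one row per (neuron, basis center):
#'   `neuron_id`, `site_id`, `center_x`, `center_y`, carrying the basis
#'   parameters as attributes `length_scale`, `q`, `inclusion_radius`.
#' @export
build_basis_sets <- function(centroids, sites, length_scale = 6, q = 2,
                             inclusion_radius = 30) {
  check_basis_params(length_scale, q)
  if (inclusion_radius <= 0) abort("`inclusion_radius` must be positive.")
  centroids <- validate_centroids(centroids)
  if (nrow(sites) == 0L) {
    warn("No stimulation sites supplied; all basis sets are empty.")
    out <- tibble::tibble(
      neuron_id = centroids$neuron_id[0], site_id = integer(),
      center_x = double(), center_y = double()
    )
  } else {
    cm <- cbind(centroids$x_um, centroids$y_um)
    sm <- cbind(sites$x_um, sites$y_um)
    d2 <- pairwise_sq_dist(cm, sm)
    hit <- which(d2 <= inclusion_radius^2, arr.ind = TRUE)
    out <- tibble::tibble(
      neuron_id = centroids$neuron_id[hit[, 1L]],
      site_id = sites$site_id[hit[, 2L]],
      center_x = sites$x_um[hit[, 2L]],
      center_y = sites$y_um[hit[, 2L]]
    )
    out <- dplyr::arrange(out, match(.data$neuron_id, centroids$neuron_id), .data$site_id)
  }
  attr(out, "length_scale") <- length_scale
  attr(out, "q") <- q
  attr(out, "inclusion_radius") <- inclusion_radius
  out
}

#' Build the NBFR design matrix for one neuron
#'
#' Entry `(k, m)` is the total contribution of basis function `m` to the
#' neuron's response on trial `k`: the basis evaluated at each of the trial's
#' J holographic targets and summed. Each entry therefore lies in `[0, J]`.
#'
#' @param centers M x 2 matrix (or tibble with `center_x`, `center_y`) of the
#'   neuron's basis centers (microns).
#' @param protocol A `stim_protocol` object, or a list of J x 2 pattern
#'   matrices (one per trial).
#' @param length_scale,q Basis parameters.
#' @return A K x M numeric matrix.
#' @export
build_design_matrix <- function(centers, protocol, length_scale = 6, q = 2) {
  check_basis_params(length_scale, q)
  if (is.data.frame(centers)) {
    centers <- as.matrix(centers[, c("center_x", "center_y")])
  }
  if (is.matrix(centers) && nrow(centers) == 0L) {
    abort("Empty basis set: neuron is unmappable (no design matrix).")
  }
  centers <- as_pattern_matrix(centers)
  patterns <- protocol_patterns(protocol)
  if (length(patterns) == 0L) abort("`protocol` contains no trials.")
  targets <- do.call(rbind, patterns)
  trial_of <- rep(seq_along(patterns), vapply(patterns, nrow, 1L))
  d2 <- pairwise_sq_dist(targets, centers)
  phi <- basis_value_sq(d2, length_scale, q)
  out <- rowsum(phi, trial_of, reorder = TRUE)
  dimnames(out) <- NULL
  out
}

# Extract the list of J x 2 target matrices from a protocol-like object.
protocol_patterns <- function(protocol) {
  if (inherits(protocol, "stim_protocol")) {
    trials <- protocol$trials
    return(lapply(split(trials, trials$trial)[as.character(sort(unique(trials$trial)))],
                  function(tr) as_pattern_matrix(tr[, c("x_um", "y_um")])))
  }
  if (is.list(protocol) && !is.data.frame(protocol)) {
    return(lapply(protocol, as_pattern_matrix))
  }
  list(as_pattern_matrix(protocol))
}
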