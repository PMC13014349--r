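#' Sample neuron centroids uniformly in a square FOV
#'
#' @param n_neurons Number of neurons.
#' @param fov_um Side length of the square field of view in microns
#'   (default 411).
#' @param seed Optional integer seed.
#' @return A centroid tibble (`neuron_id`, `x_um`, `y_um`).
#' @export
sample_population <- function(n_neurons, fov_um = 411, seed = NULL) {
  if (n_neurons < 1) abort("`n_neurons` must be >= 1.")
  with_preserved_seed(seed, {
    out <- tibble::tibble(
      neuron_id = seq_len(n_neurons),
      x_um = runif(n_neurons, 0, fov_um),
      y_um = runif(n_neurons, 0, fov_um)
    )
    attr(out, "fov_um") <- fov_um
    out
  })
}

#' Sample heterogeneous ground-truth optogenetic receptive fields
#'
#' Each neuron's true ORF is a non-negative mixture of super-Gaussian radial
#' bases: a random number of components, each with a random center near the
#' soma, random width and random positive weight, rescaled so the ORF's peak
#' over a fine spatial grid equals 1 (normalized response units). The default
#' exponent `q = 4` produces the flat-topped, sharp-edged profiles seen in
#' direct recordings; the deliberate mismatch with the `q = 2` fitting basis
#' is part of the benchmark conditions.
#'
#' @param centroids Centroid tibble.
#' @param q Ground-truth basis exponent (default 4).
#' @param n_bases_range Integer range for the number of mixture components
#'   per neuron (default `c(1, 4)`).
#' @param width_range Range of component length scales in microns
#'   (default `c(4, 10)`).
#' @param offset_range Maximum distance (microns) of a component center from
#'   the soma centroid; centers are uniform in that disc. Default 10.
#' @param noise_sd Imaging-noise standard deviation attached to the
#'   population (used by [simulate_responses()]). Default 0.25.
#' @param norm_grid_um Spacing of the normalization grid (default 0.5).
#' @param seed Optional integer seed.
#' @return An object of class `orf_population`: list with `centroids`,
#'   `bases` (tibble `neuron_id`, `center_x`, `center_y`, `width`, `weight`),
#'   `q`, `fov_um`, `noise_sd`.
#' @export
sample_ground_truth_orfs <- function(centroids, q = 4, n_bases_range = c(1, 4),
                                     width_range = c(4, 10), offset_range = 10,
                                     noise_sd = 0.25, norm_grid_um = 0.5,
                                     seed = NULL) {
  if (any(width_range <= 0) || offset_range < 0) {
    abort("ORF width and offset ranges must be positive.")
  }
  centroids <- validate_centroids(centroids)
  with_preserved_seed(seed, {
    n <- nrow(centroids)
    counts <- sample(seq(n_bases_range[1], n_bases_range[2]), n, replace = TRUE)
    total <- sum(counts)
    # centers uniform in the disc of radius offset_range around the soma
    ang <- runif(total, 0, 2 * pi)
    rad <- offset_range * sqrt(runif(total))
    bases <- tibble::tibble(
      neuron_id = rep(centroids$neuron_id, counts),
      center_x = rep(centroids$x_um, counts) + rad * cos(ang),
      center_y = rep(centroids$y_um, counts) + rad * sin(ang),
      width = runif(total, width_range[1], width_range[2]),
      weight = runif(total)
    )
    # normalize each ORF to unit peak: coarse grid search over the component
    # hull (the peak of a positive mixture of radial bases lies inside it),
    # refined by continuous maximization from the best grid point
    bl <- split(bases, factor(bases$neuron_id, levels = centroids$neuron_id))
    peaks <- vapply(seq_len(n), function(i) {
      b <- bl[[i]]
      eval_neg <- function(x) {
        d2 <- (b$center_x - x[1L])^2 + (b$center_y - x[2L])^2
        -sum(b$weight * exp(-d2^(q / 2) / (2 * b$width^q)))
      }
      pad <- 2
      gx <- seq(min(b$center_x) - pad, max(b$center_x) + pad, by = norm_grid_um)
      gy <- seq(min(b$center_y) - pad, max(b$center_y) + pad, by = norm_grid_um)
      pts <- cbind(rep(gx, length(gy)), rep(gy, each = length(gx)))
      d2 <- pairwise_sq_dist(pts, cbind(b$center_x, b$center_y))
      phi <- exp(-sweep_width(d2, b$width, q) / 2)
      vals <- drop(phi %*% b$weight)
      ref <- stats::optim(pts[which.max(vals), ], eval_neg, method = "Nelder-Mead",
                          control = list(reltol = 1e-10))
      max(max(vals), -ref$value)
    }, 1.0)
    bases$weight <- bases$weight / rep(peaks, counts)
    structure(
      list(centroids = centroids, bases = bases, q = q,
           fov_um = attr(centroids, "fov_um") %||% NA_real_,
           noise_sd = noise_sd),
      class = "orf_population"
    )
  })
}

#' Simulate a ground-truth population in one call
#'
#' @inheritParams sample_population
#' @inheritParams sample_ground_truth_orfs
#' @param ... Passed on to [sample_ground_truth_orfs()].
#' @return An `orf_population`.
#' @export
simulate_population <- function(n_neurons = 300, fov_um = 411, noise_sd = 0.25,
                                seed = NULL, ...) {
  with_preserved_seed(seed, {
    cent <- sample_population(n_neurons, fov_um)
    sample_ground_truth_orfs(cent, noise_sd = noise_sd, ...)
  })
}

#' @export
print.orf_population <- function(x, ...) {
  cat(sprintf("<orf_population> %d neurons in a %g um FOV; q = %g, noise sd = %g\n",
              nrow(x$centroids), x$fov_um, x$q, x$noise_sd))
  invisible(x)
}

#' @export
orf_bases.orf_population <- function(object) {
  b <- object$bases
  attr(b, "q") <- object$q
  b
}

#' @export
orf_neuron_ids.orf_population <- function(object) object$centroids$neuron_id

#' @export
orf_centroids.orf_population <- function(object) {
  object$centroids[, c("neuron_id", "x_um", "y_um")]
}

#' Simulate noisy population responses to a mapping protocol
#'
#' Each neuron's response on each trial is its noiseless ORF drive (the
#' ground-truth ORF summed over the trial's holographic targets) plus
#' independent additive Gaussian imaging noise.
#'
#' @param truth An `orf_population`.
#' @param protocol A `stim_protocol` or list of pattern matrices.
#' @param noise_sd Imaging noise SD; defaults to the population's.
#' @param seed Optional integer seed.
#' @return A K x N response matrix with neuron ids as column names.
#' @export
simulate_responses <- function(truth, protocol, noise_sd = truth$noise_sd,
                               seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  with_preserved_seed(seed, {
    drive <- orf_drive_matrix(truth, protocol)
    drive + rnorm(length(drive), 0, noise_sd)
  })
}

#' Average repeated runs of a mapping protocol
#'
#' Simulates `repetitions` independent noisy response matrices for the same
#' protocol and averages them per (trial, neuron); the effective noise SD
#' shrinks by `1/sqrt(repetitions)` while the ORF drive is unchanged.
#'
#' @inheritParams simulate_responses
#' @param repetitions Number of repetitions (>= 1).
#' @return A K x N averaged response matrix.
#' @export
repetition_averaging <- function(truth, protocol, repetitions = 1,
                                 noise_sd = truth$noise_sd, seed = NULL) {
  if (repetitions < 1) abort("`repetitions` must be >= 1.")
  with_preserved_seed(seed, {
    drive <- orf_drive_matrix(truth, protocol)
    acc <- matrix(0, nrow(drive), ncol(drive))
    for (r in seq_len(repetitions)) {
      acc <- acc + rnorm(length(drive), 0, noise_sd)
    }
    drive + acc / repetitions
  })
}

#' Sample a target ensemble of graded spatial compactness
#'
#' Picks a uniform center neuron, then draws the remaining members without
#' replacement with probability proportional to `exp(-lambda * distance)` from
#' the center neuron. `lambda = 1` gives compact ensembles (nearest
#' neighbours); `lambda = 0.01` gives diffuse, near-uniform ensembles.
#'
#' @param centroids Centroid tibble (or an `orf_population`).
#' @param size Ensemble size (including the center neuron).
#' @param lambda Compactness weight in 1/microns (default 0.01, diffuse).
#' @param seed Optional integer seed.
#' @return An integer/character vector of `size` neuron ids.
#' @export
sample_ensemble <- function(centroids, size, lambda = 0.01, seed = NULL) {
  if (inherits(centroids, "orf_population")) centroids <- centroids$centroids
  centroids <- validate_centroids(centroids)
  n <- nrow(centroids)
  if (size > n) abort("Ensemble `size` exceeds the population size.")
  with_preserved_seed(seed, {
    c_idx <- sample.int(n, 1L)
    if (size == 1L) return(centroids$neuron_id[c_idx])
    d <- sqrt((centroids$x_um - centroids$x_um[c_idx])^2 +
                (centroids$y_um - centroids$y_um[c_idx])^2)
    # log-scale weights survive lambda * d >> 700 where exp() underflows
    logw <- -lambda * d
    logw[c_idx] <- -Inf
    rest <- integer(size - 1L)
    avail <- setdiff(seq_len(n), c_idx)
    for (i in seq_len(size - 1L)) {
      w <- exp(logw[avail] - max(logw[avail]))
      pick <- avail[sample.int(length(avail), 1L, prob = w)]
      rest[i] <- pick
      avail <- setdiff(avail, pick)
    }
    centroids$neuron_id[c(c_idx, rest)]
  })
}

#' Sample sparse excitatory functional connectivity
#'
#' Off-diagonal strengths are drawn from a zero-inflated exponential: zero
#' with probability `1 - p_cnx`, otherwise exponential with mean `gamma`.
#' The diagonal is zero.
#'
#' @param n_neurons Population size.
#' @param p_cnx Connection probability (default 0.05).
#' @param gamma Mean connection strength in normalized response units
#'   (typical sweep: 0.001, 0.01, 0.1, 1).
#' @param seed Optional integer seed.
#' @return An `n x n` matrix of strengths `r[m, n]` (from neuron m to n).
#' @export
sample_connectivity <- function(n_neurons, p_cnx = 0.05, gamma, seed = NULL) {
  if (p_cnx < 0 || p_cnx > 1) abort("`p_cnx` must be in [0, 1].")
  if (gamma <= 0) abort("`gamma` must be positive.")
  with_preserved_seed(seed, {
    r <- matrix(0, n_neurons, n_neurons)
    nz <- matrix(runif(n_neurons^2) < p_cnx, n_neurons, n_neurons)
    diag(nz) <- FALSE
    r[nz] <- rexp(sum(nz), rate = 1 / gamma)
    r
  })
}

#' Simulate mapping responses with recurrent excitation
#'
#' One synchronous round of functional recurrence on top of the direct
#' optogenetic drive: on each trial each neuron emits a spike train with
#' probability `sigmoid(theta0 * drive - theta1)` (stimulation near the ORF
#' peak makes transmission likely), and every postsynaptic partner receives
#' the presynaptic connection strength. With a zero connectome this reduces
#' exactly to [simulate_responses()].
#'
#' @inheritParams simulate_responses
#' @param connectome Matrix from [sample_connectivity()].
#' @param theta0 Sigmoid coefficient (default 0.85).
#' @param theta1 Sigmoid threshold (default 3).
#' @return A K x N response matrix.
#' @export
simulate_with_recurrence <- function(truth, connectome, protocol,
                                     theta0 = 0.85, theta1 = 3,
                                     noise_sd = truth$noise_sd, seed = NULL) {
  n <- nrow(truth$centroids)
  if (!is.matrix(connectome) || any(dim(connectome) != n)) {
    abort("`connectome` must be an N x N matrix matching the population.")
  }
  with_preserved_seed(seed, {
    drive <- orf_drive_matrix(truth, protocol)
    # noise drawn first so that, under a shared seed, a zero connectome
    # reproduces simulate_responses() exactly
    noise <- rnorm(length(drive), 0, noise_sd)
    p_spike <- plogis(theta0 * drive - theta1)
    s <- matrix(rbinom(length(drive), 1L, p_spike), nrow(drive), ncol(drive))
    recurrent <- s %*% connectome # [k, n] = sum_m s[k, m] r[m, n]
    drive + recurrent + noise
  })
}

#' Neurons activated by a stimulation pattern
#'
#' A neuron counts as activated when its noiseless direct ORF drive (summed
#' over the pattern's targets) reaches `threshold`. Benchmark scoring always
#' uses the ground-truth ORFs and noiseless drive, so that the measured
#' off-target effects isolate direct optical off-target stimulation.
#'
#' @param truth An `orf_population` (or an `nbfr_fit`, for model-predicted
#'   activation).
#' @param pattern A J x 2 stimulation pattern.
#' @param threshold Activation threshold in normalized response units
#'   (default 0.5, half the normalized ORF peak).
#' @return The vector of activated neuron ids (possibly empty).
#' @export
evaluate_activation <- function(truth, pattern, threshold = 0.5) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  if (is.null(pattern) || (is.matrix(pattern) && nrow(pattern) == 0L)) {
    return(orf_neuron_ids(truth)[0])
  }
  pred <- predict_response(truth, pattern)
  pred$neuron_id[pred$response >= threshold]
}
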