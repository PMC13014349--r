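#' Fit one neuron's ORF weights by non-negative least squares
#'
#' Solves \eqn{\hat{w} = \arg\min_w \lVert y - \Phi w \rVert^2} subject to
#' \eqn{w \ge 0} (Lawson-Hanson active set, via [pracma::lsqnonneg()]).
#' Non-negativity of the weights is what keeps out-of-sample ORF predictions
#' physically plausible (an optogenetic drive cannot be negative). The
#' residual-noise estimate is retained for diagnostics only.
#'
#' @param design K x M design matrix from [build_design_matrix()].
#' @param responses Length-K vector of evoked-response scalars (one per trial,
#'   arbitrary fluorescence units such as z-scored dF/F).
#' @return A list with elements `weights` (M non-negative scalars),
#'   `noise_sd` (residual root-mean-square), `fitted` (length-K vector) and
#'   `objective` (residual sum of squares).
#' @export
fit_nbfr <- function(design, responses) {
  if (!is.matrix(design) || !all(is.finite(design))) {
    abort("`design` must be a finite numeric matrix.")
  }
  responses <- as.numeric(responses)
  if (length(responses) != nrow(design)) {
    abort(sprintf("Length of `responses` (%d) does not match design rows (%d).",
                  length(responses), nrow(design)))
  }
  if (all(responses == 0)) {
    w <- rep(0, ncol(design))
  } else {
    w <- pracma::lsqnonneg(design, responses)$x
    w[w < 0] <- 0 # guard against solver round-off
  }
  fitted <- drop(design %*% w)
  res <- responses - fitted
  list(
    weights = w,
    noise_sd = sqrt(mean(res^2)),
    fitted = fitted,
    objective = sum(res^2)
  )
}

#' Fit NBFR models for a whole population
#'
#' Builds each neuron's adaptive basis set from the retained stimulation
#' sites, assembles its design matrix over the mapping protocol, and solves
#' the per-neuron non-negative least squares problem. Neurons whose fitted ORF
#' never exceeds `min_evoked` at any basis center are flagged not excitable
#' and are excluded from downstream optimization.
#'
#' For speed, a neuron's design matrix only includes trials that stimulated
#' within `inclusion_radius + trial_margin` microns of its centroid; beyond
#' that distance every basis value is below 2e-4 and the trial carries no
#' information about the neuron (see the methods vignette).
#'
#' @inheritParams build_basis_sets
#' @param protocol A `stim_protocol` (or list of pattern matrices).
#' @param responses K x N response matrix (trials x neurons); columns are
#'   matched to `centroids$neuron_id` by column name when present, otherwise
#'   by position.
#' @param min_evoked Excitability threshold on the fitted ORF amplitude
#'   (normalized response units). Default 0.1.
#' @param trial_margin Extra radius (microns) beyond `inclusion_radius` for
#'   including trials in a neuron's fit. Default 25.
#' @return An object of class `nbfr_fit`: a list with tibbles `neurons`
#'   (`neuron_id`, `x_um`, `y_um`, `n_bases`, `noise_sd`, `amplitude`,
#'   `excitable`) and `bases` (`neuron_id`, `site_id`, `center_x`, `center_y`,
#'   `weight`), plus `params`.
#' @export
fit_orfs <- function(centroids, sites, protocol, responses,
                     length_scale = 6, q = 2, inclusion_radius = 30,
                     min_evoked = 0.1, trial_margin = 25) {
  centroids <- validate_centroids(centroids)
  basis <- build_basis_sets(centroids, sites, length_scale, q, inclusion_radius)
  patterns <- protocol_patterns(protocol)
  K <- length(patterns)
  responses <- as.matrix(responses)
  if (nrow(responses) != K) {
    abort(sprintf("`responses` has %d rows but the protocol has %d trials.",
                  nrow(responses), K))
  }
  col_of <- if (!is.null(colnames(responses))) {
    match(as.character(centroids$neuron_id), colnames(responses))
  } else {
    seq_len(nrow(centroids))
  }
  if (anyNA(col_of) || ncol(responses) < nrow(centroids)) {
    abort("`responses` columns do not cover all neurons in `centroids`.")
  }

  targets <- do.call(rbind, patterns)
  trial_of <- rep(seq_len(K), vapply(patterns, nrow, 1L))
  basis_by_neuron <- split(basis, factor(basis$neuron_id, levels = centroids$neuron_id))
  reach2 <- (inclusion_radius + trial_margin)^2

  fits <- purrr::map(seq_len(nrow(centroids)), function(i) {
    b <- basis_by_neuron[[i]]
    if (is.null(b) || nrow(b) == 0L) {
      return(list(weights = double(), noise_sd = NA_real_, site_id = integer(),
                  centers = matrix(numeric(), 0, 2)))
    }
    ctr <- c(centroids$x_um[i], centroids$y_um[i])
    near <- (targets[, 1L] - ctr[1L])^2 + (targets[, 2L] - ctr[2L])^2 <= reach2
    rows <- unique(trial_of[near])
    if (length(rows) == 0L) rows <- 1L
    keep <- trial_of %in% rows
    d2 <- pairwise_sq_dist(targets[keep, , drop = FALSE],
                           cbind(b$center_x, b$center_y))
    phi <- basis_value_sq(d2, length_scale, q)
    Phi <- rowsum(phi, trial_of[keep], reorder = TRUE)
    y <- responses[sort(rows), col_of[i]]
    f <- fit_nbfr(unname(Phi), y)
    list(weights = f$weights, noise_sd = f$noise_sd, site_id = b$site_id,
         centers = cbind(b$center_x, b$center_y))
  })

  bases <- tibble::tibble(
    neuron_id = rep(centroids$neuron_id, vapply(fits, function(f) length(f$weights), 1L)),
    site_id = unlist(lapply(fits, `[[`, "site_id")),
    center_x = unlist(lapply(fits, function(f) f$centers[, 1L])),
    center_y = unlist(lapply(fits, function(f) f$centers[, 2L])),
    weight = unlist(lapply(fits, `[[`, "weights"))
  )
  neurons <- tibble::tibble(
    neuron_id = centroids$neuron_id,
    x_um = centroids$x_um,
    y_um = centroids$y_um,
    n_bases = vapply(fits, function(f) length(f$weights), 1L),
    noise_sd = vapply(fits, `[[`, 1.0, "noise_sd")
  )
  out <- structure(
    list(neurons = neurons, bases = bases,
         params = list(length_scale = length_scale, q = q,
                       inclusion_radius = inclusion_radius,
                       min_evoked = min_evoked, trial_margin = trial_margin)),
    class = "nbfr_fit"
  )
  flag_excitable(out, min_evoked)
}

#' Flag neurons as excitable or not
#'
#' A neuron is deemed not excitable when its maximum fitted ORF amplitude over
#' its own basis centers falls below `min_evoked`; such neurons (typically
#' opsin-negative or unmapped) are excluded from stimulus optimization and
#' ensemble selection.
#'
#' @param fit An `nbfr_fit` object.
#' @param min_evoked Amplitude threshold (normalized response units).
#' @return The fit with updated `neurons$amplitude` and `neurons$excitable`.
#' @export
flag_excitable <- function(fit, min_evoked = fit$params$min_evoked) {
  stopifnot(inherits(fit, "nbfr_fit"))
  p <- fit$params
  amp <- vapply(split(fit$bases, factor(fit$bases$neuron_id, levels = fit$neurons$neuron_id)),
                function(b) {
                  if (is.null(b) || nrow(b) == 0L) return(0)
                  cm <- cbind(b$center_x, b$center_y)
                  phi <- basis_value_sq(pairwise_sq_dist(cm, cm), p$length_scale, p$q)
                  max(drop(phi %*% b$weight))
                }, 1.0)
  fit$neurons$amplitude <- unname(amp)
  fit$neurons$excitable <- unname(amp) >= min_evoked
  fit$params$min_evoked <- min_evoked
  fit
}

#' @export
print.nbfr_fit <- function(x, ...) {
  cat(sprintf(
    "<nbfr_fit> %d neurons (%d excitable), %d basis functions; l = %g um, q = %g, d = %g um\n",
    nrow(x$neurons), sum(x$neurons$excitable), nrow(x$bases),
    x$params$length_scale, x$params$q, x$params$inclusion_radius))
  invisible(x)
}

#' Predict population responses to a stimulation pattern
#'
#' Evaluates each neuron's fitted ORF at every holographic target of the
#' pattern and sums: the model's expected (noiseless) evoked response. All
#' predictions are non-negative by construction.
#'
#' @param fit An `nbfr_fit` object (or a ground-truth `orf_population`).
#' @param pattern A J x 2 pattern (matrix, tibble or length-2 vector).
#' @return A tibble with columns `neuron_id`, `response`.
#' @export
predict_response <- function(fit, pattern) {
  pattern <- as_pattern_matrix(pattern)
  b <- orf_bases(fit)
  ids <- orf_neuron_ids(fit)
  if (nrow(b) == 0L) {
    return(tibble::tibble(neuron_id = ids, response = 0))
  }
  d2 <- pairwise_sq_dist(pattern, cbind(b$center_x, b$center_y))
  phi <- basis_value_sq(sweep_width(d2, b$width, attr(b, "q")), 1, 2) # see sweep_width
  per_basis <- colSums(phi) * b$weight
  resp <- rowsum(per_basis, factor(b$neuron_id, levels = ids))
  tibble::tibble(neuron_id = ids, response = as.numeric(resp[match(ids, rownames(resp))]))
}

# Transform squared distances so that exp(-t/2) with unit scale reproduces
# exp(-d^q / (2 w^q)) for per-basis widths w: t = (d^2)^(q/2) / w^q, applied
# column-wise. Keeps one vectorized exp() path for truth (q=4, mixed widths)
# and fits (q=2, shared length scale).
sweep_width <- function(d2, width, q) {
  t(t(d2^(q / 2)) / width^q)
}

# --- shared ORF-evaluation surface -----------------------------------------

# Both fitted models and ground-truth populations expose their ORFs as a flat
# table of weighted radial bases: neuron_id, center_x, center_y, weight, width
# (basis length scale, microns), with the exponent as attribute "q".
orf_bases <- function(object) UseMethod("orf_bases")

#' @export
orf_bases.nbfr_fit <- function(object) {
  b <- object$bases
  b$width <- object$params$length_scale
  attr(b, "q") <- object$params$q
  b
}

orf_neuron_ids <- function(object) UseMethod("orf_neuron_ids")

#' @export
orf_neuron_ids.nbfr_fit <- function(object) object$neurons$neuron_id

orf_centroids <- function(object) UseMethod("orf_centroids")

#' @export
orf_centroids.nbfr_fit <- function(object) {
  object$neurons[, c("neuron_id", "x_um", "y_um")]
}

# Noiseless drive of every neuron for every trial of a protocol: K x N matrix.
# Per neuron, only targets within reach of its basis support are evaluated;
# the omitted contributions are below exp(-...) ~ 1e-11 at the default cutoff.
orf_drive_matrix <- function(object, protocol) {
  patterns <- protocol_patterns(protocol)
  K <- length(patterns)
  targets <- do.call(rbind, patterns)
  trial_of <- rep(seq_len(K), vapply(patterns, nrow, 1L))
  b <- orf_bases(object)
  q <- attr(b, "q")
  cent <- orf_centroids(object)
  ids <- cent$neuron_id
  out <- matrix(0, K, length(ids), dimnames = list(NULL, as.character(ids)))
  if (nrow(b) == 0L) return(out)
  bl <- split(b, factor(b$neuron_id, levels = ids))
  for (i in seq_along(ids)) {
    bi <- bl[[i]]
    if (is.null(bi) || nrow(bi) == 0L) next
    ctr <- c(cent$x_um[i], cent$y_um[i])
    off <- sqrt(max((bi$center_x - ctr[1L])^2 + (bi$center_y - ctr[2L])^2))
    tail <- max(bi$width) * (2 * log(1e11))^(1 / q)
    reach2 <- (off + tail)^2
    near <- (targets[, 1L] - ctr[1L])^2 + (targets[, 2L] - ctr[2L])^2 <= reach2
    if (!any(near)) next
    d2 <- pairwise_sq_dist(targets[near, , drop = FALSE], cbind(bi$center_x, bi$center_y))
    phi <- exp(-sweep_width(d2, bi$width, q) / 2)
    drive <- rowsum(drop(phi %*% bi$weight), trial_of[near])
    out[as.integer(rownames(drive)), i] <- drive
  }
  out
}

#' Evaluate one neuron's ORF at arbitrary points
#'
#' Works for both fitted models (`nbfr_fit`) and ground-truth populations
#' (`orf_population`).
#'
#' @param object Model or ground-truth object.
#' @param neuron_id Which neuron's ORF to evaluate.
#' @param points P x 2 matrix of (x_um, y_um) query points.
#' @return A length-P vector of non-negative ORF values.
#' @export
orf_value <- function(object, neuron_id, points) {
  points <- as_pattern_matrix(points)
  b <- orf_bases(object)
  q <- attr(b, "q")
  b <- b[b$neuron_id == neuron_id, , drop = FALSE]
  if (nrow(b) == 0L) return(rep(0, nrow(points)))
  d2 <- pairwise_sq_dist(points, cbind(b$center_x, b$center_y))
  drop(exp(-sweep_width(d2, b$width, q) / 2) %*% b$weight)
}
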