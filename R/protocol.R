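#' Lay down per-neuron stimulation grids
#'
#' Positions a square lattice of candidate stimulation sites over each
#' neuron's centroid, covering `-extent` to `+extent` microns in steps of
#' `step` along each axis (defaults give a 5 x 5 grid of 25 sites per neuron,
#' one exactly at the centroid).
#'
#' @param centroids Tibble with `neuron_id`, `x_um`, `y_um`.
#' @param extent Half-width of the grid in microns (default 16).
#' @param step Lattice step in microns (default 8); `extent` must be an
#'   integer multiple of `step`.
#' @return A tibble of stimulation sites: `site_id`, `parent_id`, `x_um`,
#'   `y_um`, `offset_x`, `offset_y`.
#' @export
make_grids <- function(centroids, extent = 16, step = 8) {
  if (extent <= 0 || step <= 0) abort("`extent` and `step` must be positive.")
  if (abs(extent / step - round(extent / step)) > 1e-9) {
    abort("`extent` must be an integer multiple of `step`.")
  }
  centroids <- validate_centroids(centroids)
  offs <- seq(-extent, extent, by = step)
  lattice <- expand.grid(offset_x = offs, offset_y = offs)
  n <- nrow(centroids)
  m <- nrow(lattice)
  out <- tibble::tibble(
    site_id = seq_len(n * m),
    parent_id = rep(centroids$neuron_id, each = m),
    x_um = rep(centroids$x_um, each = m) + rep(lattice$offset_x, n),
    y_um = rep(centroids$y_um, each = m) + rep(lattice$offset_y, n),
    offset_x = rep(lattice$offset_x, n),
    offset_y = rep(lattice$offset_y, n)
  )
  out
}

#' Remove cross-grid redundant stimulation sites
#'
#' Visits all sites in a random order, retaining a site unless it lies within
#' `min_separation` microns of an already-retained site belonging to a
#' different neuron's grid; same-grid pairs are exempt (the 8 um lattice step
#' keeps them apart anyway). The result is order-dependent but fully
#' reproducible given the seed. Where grids from neighbouring neurons overlap
#' this removes roughly half of the overlapping sites, which is what makes
#' ensemble ORF mapping scale sublinearly with population size.
#'
#' @param sites Site tibble from [make_grids()].
#' @param min_separation Minimum cross-grid separation in microns (default 5).
#' @param seed Optional integer seed for the removal order (the session RNG is
#'   used, and restored, when given).
#' @return The retained subset of `sites` (original row order preserved).
#' @export
remove_redundant_sites <- function(sites, min_separation = 5, seed = NULL) {
  if (min_separation <= 0) abort("`min_separation` must be positive.")
  n <- nrow(sites)
  if (n == 0L) return(sites)
  with_preserved_seed(seed, {
    ord <- sample.int(n)
    cell <- min_separation
    kx <- floor(sites$x_um / cell)
    ky <- floor(sites$y_um / cell)
    keykey <- paste(kx, ky)
    retained <- logical(n)
    bins <- new.env(hash = TRUE, parent = emptyenv())
    x <- sites$x_um; y <- sites$y_um; parent <- sites$parent_id
    r2 <- min_separation^2
    for (i in ord) {
      ok <- TRUE
      for (ax in (kx[i] - 1L):(kx[i] + 1L)) {
        for (ay in (ky[i] - 1L):(ky[i] + 1L)) {
          ids <- bins[[paste(ax, ay)]]
          if (!is.null(ids)) {
            for (j in ids) {
              if (parent[j] != parent[i] &&
                  (x[j] - x[i])^2 + (y[j] - y[i])^2 < r2) {
                ok <- FALSE
                break
              }
            }
          }
          if (!ok) break
        }
        if (!ok) break
      }
      if (ok) {
        retained[i] <- TRUE
        bins[[keykey[i]]] <- c(bins[[keykey[i]]], i)
      }
    }
    sites[retained, , drop = FALSE]
  })
}

#' Batch retained sites into multi-target stimulation trials
#'
#' Partitions the retained sites into trials of (up to) `J` simultaneous
#' holographic targets, ordered so that every target of a trial is at least
#' `min_consecutive_distance` microns from every target of the immediately
#' preceding trial -- this gives evoked calcium transients time to decay
#' before a neighbourhood is revisited. Trials are drawn by rejection
#' sampling from the remaining pool; after `max_retries` rejected draws the
#' constraint is relaxed greedily (the pool sites farthest from the previous
#' trial are taken) and the relaxation is counted in the result.
#'
#' @param sites Retained site tibble.
#' @param n_targets Targets per trial `J` (default 10). The final trial may be
#'   smaller; it is emitted as-is rather than padded, so no site is stimulated
#'   twice within a repetition.
#' @param min_consecutive_distance Minimum distance (microns) between any
#'   target and any target of the previous trial. Default 30.
#' @param max_retries Rejected draws per trial before greedy relaxation.
#' @param seed Optional integer seed.
#' @return A `stim_protocol` object: list with `trials` (tibble `trial`,
#'   `slot`, `site_id`, `parent_id`, `x_um`, `y_um`), `params`, `seed`,
#'   `n_relaxed`.
#' @export
batch_into_trials <- function(sites, n_targets = 10, min_consecutive_distance = 30,
                              max_retries = 1000, seed = NULL) {
  if (n_targets < 1) abort("`n_targets` must be >= 1.")
  n <- nrow(sites)
  if (n == 0L) abort("No sites to batch into trials.")
  with_preserved_seed(seed, {
    x <- sites$x_um; y <- sites$y_um
    pool <- sample.int(n)
    d2min <- min_consecutive_distance^2
    trials <- vector("list", ceiling(n / n_targets))
    prev <- integer()
    n_relaxed <- 0L
    k <- 0L
    while (length(pool) > 0L) {
      take <- min(n_targets, length(pool))
      chosen <- NULL
      if (length(prev) == 0L) {
        chosen <- pool[seq_len(take)]
      } else {
        n_draws <- if (length(pool) == take) 1L else max_retries
        for (try in seq_len(n_draws)) {
          cand <- if (length(pool) == take) pool else pool[sample.int(length(pool), take)]
          dx2 <- outer(x[cand], x[prev], "-")^2 + outer(y[cand], y[prev], "-")^2
          if (all(dx2 >= d2min)) {
            chosen <- cand
            break
          }
        }
        if (is.null(chosen)) {
          # Greedy relaxation: take the pool sites farthest from the previous
          # trial; any remaining violations are accepted and logged.
          dmin <- sqrt(outer(x[pool], x[prev], "-")^2 + outer(y[pool], y[prev], "-")^2)
          nearest <- apply(dmin, 1L, min)
          chosen <- pool[order(nearest, decreasing = TRUE)[seq_len(take)]]
          n_relaxed <- n_relaxed + 1L
        }
      }
      k <- k + 1L
      trials[[k]] <- chosen
      pool <- setdiff(pool, chosen)
      prev <- chosen
    }
    trials <- trials[seq_len(k)]
    if (n_relaxed > 0L) {
      inform(sprintf("Inter-trial spacing constraint relaxed for %d trial(s).", n_relaxed))
    }
    trial_tbl <- tibble::tibble(
      trial = rep(seq_len(k), vapply(trials, length, 1L)),
      slot = unlist(lapply(trials, seq_along)),
      site_id = sites$site_id[unlist(trials)],
      parent_id = sites$parent_id[unlist(trials)],
      x_um = x[unlist(trials)],
      y_um = y[unlist(trials)]
    )
    structure(
      list(trials = trial_tbl,
           params = list(n_targets = n_targets,
                         min_consecutive_distance = min_consecutive_distance,
                         max_retries = max_retries),
           seed = seed,
           n_relaxed = n_relaxed),
      class = "stim_protocol"
    )
  })
}

#' @export
print.stim_protocol <- function(x, ...) {
  k <- max(x$trials$trial)
  cat(sprintf("<stim_protocol> %d trials, %d sites, J = %d, min consecutive distance = %g um%s\n",
              k, nrow(x$trials), x$params$n_targets, x$params$min_consecutive_distance,
              if (x$n_relaxed > 0) sprintf(" (%d relaxed)", x$n_relaxed) else ""))
  invisible(x)
}

#' Design a complete ORF-mapping protocol
#'
#' Convenience pipeline: per-neuron grids ([make_grids()]), cross-grid
#' redundancy removal ([remove_redundant_sites()]) and batching into
#' J-target trials ([batch_into_trials()]), all under one seed.
#'
#' @inheritParams make_grids
#' @inheritParams batch_into_trials
#' @param min_separation Cross-grid redundancy radius in microns (default 5).
#' @param seed Integer seed making the whole design reproducible.
#' @return A `stim_protocol`; the retained sites are attached as
#'   `$sites`.
#' @export
design_mapping_protocol <- function(centroids, extent = 16, step = 8,
                                    min_separation = 5, n_targets = 10,
                                    min_consecutive_distance = 30,
                                    max_retries = 1000, seed = NULL) {
  with_preserved_seed(seed, {
    sites <- make_grids(centroids, extent, step)
    retained <- remove_redundant_sites(sites, min_separation)
    protocol <- batch_into_trials(retained, n_targets, min_consecutive_distance,
                                  max_retries)
    protocol$seed <- seed
    protocol$params$extent <- extent
    protocol$params$step <- step
    protocol$params$min_separation <- min_separation
    protocol$sites <- retained
    protocol
  })
}

#' Number of trials and wall-clock duration of a mapping protocol
#'
#' @param protocol A `stim_protocol`.
#' @param stim_rate_hz Stimulation rate in trials per second (default 1).
#' @param repetitions Number of repetitions of the full protocol.
#' @return A one-row tibble with `n_trials` and `seconds`.
#' @export
estimate_mapping_duration <- function(protocol, stim_rate_hz = 1, repetitions = 1) {
  if (stim_rate_hz <= 0) abort("`stim_rate_hz` must be positive.")
  n <- max(protocol$trials$trial) * repetitions
  tibble::tibble(n_trials = n, seconds = n / stim_rate_hz)
}
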