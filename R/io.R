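# Artifact plumbing. Tables travel as delimited text (header-keyed CSV),
# structured objects as JSON with a format_version field; readers reject
# unknown versions and fail cleanly on truncated files.

FORMAT_VERSION <- "1"

#' Read / write neuron centroid tables
#'
#' Delimited text with header columns `neuron_id`, `x_um`, `y_um` (any column
#' order), as produced by calcium-imaging segmentation; for standard
#' segmentation output, take each ROI's median pixel coordinates and multiply
#' by the pixel size in microns.
#'
#' @param path File path.
#' @return `read_centroids()`: a validated centroid tibble.
#' @export
read_centroids <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("neuron_id", "x_um", "y_um"), names(tbl))
  if (length(missing) > 0L) {
    abort(sprintf("Centroid file %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  for (col in c("x_um", "y_um")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tbl[[col]]))))
    if (length(bad) > 0L) {
      abort(sprintf("Non-numeric %s in centroid file %s at data line %d.",
                    col, path, bad[1L]))
    }
    tbl[[col]] <- as.numeric(tbl[[col]])
  }
  validate_centroids(tbl[, c("neuron_id", "x_um", "y_um")])
}

#' @rdname read_centroids
#' @param centroids Centroid tibble.
#' @export
write_centroids <- function(centroids, path) {
  centroids <- validate_centroids(centroids)
  readr::write_csv(centroids[, c("neuron_id", "x_um", "y_um")], path)
  invisible(path)
}

#' Read / write trial-by-neuron response matrices
#'
#' Delimited text: one row per trial, a `trial_id` column followed by one
#' column per neuron (header row carries the neuron ids).
#'
#' @param path File path.
#' @return `read_responses()`: a K x N numeric matrix with neuron-id column
#'   names and trial ids as row names.
#' @export
read_responses <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"trial_id" %in% names(tbl)) {
    abort(sprintf("Response file %s lacks a trial_id column.", path))
  }
  m <- as.matrix(tbl[, setdiff(names(tbl), "trial_id"), drop = FALSE])
  if (!is.numeric(m) || !all(is.finite(m))) {
    abort(sprintf("Response file %s contains non-finite or non-numeric entries.", path))
  }
  rownames(m) <- tbl$trial_id
  m
}

#' @rdname read_responses
#' @param responses K x N response matrix.
#' @export
write_responses <- function(responses, path) {
  responses <- as.matrix(responses)
  if (is.null(colnames(responses))) {
    colnames(responses) <- seq_len(ncol(responses))
  }
  tbl <- tibble::as_tibble(responses)
  tbl <- dplyr::bind_cols(tibble::tibble(trial_id = rownames(responses) %||%
                                           seq_len(nrow(responses))), tbl)
  readr::write_csv(tbl, path)
  invisible(path)
}

read_versioned_json <- function(path, kind) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(sprintf("Cannot parse %s (%s): %s", path, kind,
                                  conditionMessage(e)))
                  })
  if (!identical(obj$format_version, FORMAT_VERSION)) {
    abort(sprintf("%s has format_version '%s'; this build reads version '%s'.",
                  path, obj$format_version %||% "<missing>", FORMAT_VERSION))
  }
  if (!identical(obj$kind, kind)) {
    abort(sprintf("%s holds a '%s' artifact, expected '%s'.",
                  path, obj$kind %||% "<missing>", kind))
  }
  obj
}

write_versioned_json <- function(x, path, kind) {
  x <- c(list(format_version = FORMAT_VERSION, kind = kind), x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read / write mapping protocols
#'
#' JSON with the design seed, grid parameters and the ordered trials (each a
#' set of sites with ids, parents and coordinates). [export_protocol_table()]
#' additionally writes a flat CSV (`trial_id`, `slot`, `x_um`, `y_um`) for
#' rig import.
#'
#' @param path File path.
#' @return `read_protocol()`: a `stim_protocol`.
#' @export
read_protocol <- function(path) {
  obj <- read_versioned_json(path, "stim_protocol")
  trials <- tibble::as_tibble(obj$trials)
  n_targets <- obj$params$n_targets
  over <- trials |> dplyr::count(.data$trial) |> dplyr::filter(.data$n > n_targets)
  if (nrow(over) > 0L) {
    abort(sprintf("Protocol %s: trial %d has %d sites but J = %d.",
                  path, over$trial[1L], over$n[1L], n_targets))
  }
  structure(
    list(trials = trials, params = obj$params,
         seed = obj$seed, n_relaxed = obj$n_relaxed %||% 0L,
         sites = if (!is.null(obj$sites)) tibble::as_tibble(obj$sites)),
    class = "stim_protocol"
  )
}

#' @rdname read_protocol
#' @param protocol A `stim_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  write_versioned_json(
    list(seed = protocol$seed, params = protocol$params,
         n_relaxed = protocol$n_relaxed, trials = protocol$trials,
         sites = protocol$sites),
    path, "stim_protocol"
  )
}

#' @rdname read_protocol
#' @export
export_protocol_table <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  readr::write_csv(protocol$trials[, c("trial", "slot", "x_um", "y_um")] |>
                     dplyr::rename(trial_id = "trial"), path)
  invisible(path)
}

#' Read / write fitted NBFR models
#'
#' One JSON document per population: fit parameters, per-neuron records
#' (centroid, basis count, residual noise SD, amplitude, excitability) and
#' the flat table of basis centers with their non-negative weights.
#'
#' @param path File path.
#' @return `read_orf_fit()`: an `nbfr_fit`.
#' @export
read_orf_fit <- function(path) {
  obj <- read_versioned_json(path, "nbfr_fit")
  structure(
    list(neurons = tibble::as_tibble(obj$neurons),
         bases = tibble::as_tibble(obj$bases),
         params = obj$params),
    class = "nbfr_fit"
  )
}

#' @rdname read_orf_fit
#' @param fit An `nbfr_fit`.
#' @export
write_orf_fit <- function(fit, path) {
  stopifnot(inherits(fit, "nbfr_fit"))
  write_versioned_json(
    list(params = fit$params, neurons = fit$neurons, bases = fit$bases),
    path, "nbfr_fit"
  )
}

#' Read / write stimulus-optimization results
#'
#' JSON with the ensemble, somatic and optimized patterns, per-target
#' objective traces and optimizer settings; [export_pattern_table()] writes
#' the final coordinates as flat CSV for rig import.
#'
#' @param path File path.
#' @return `read_optimization()`: a `stim_optimization`.
#' @export
read_optimization <- function(path) {
  obj <- read_versioned_json(path, "stim_optimization")
  structure(
    list(pattern = tibble::as_tibble(obj$pattern),
         init = tibble::as_tibble(obj$init),
         objective = obj$objective, objective_init = obj$objective_init,
         traces = obj$traces,
         trajectories = lapply(obj$trajectories, function(m) {
           matrix(unlist(m), ncol = 2L, byrow = FALSE)
         }),
         converged = obj$converged, settings = obj$settings),
    class = "stim_optimization"
  )
}

#' @rdname read_optimization
#' @param result A `stim_optimization`.
#' @export
write_optimization <- function(result, path) {
  stopifnot(inherits(result, "stim_optimization"))
  write_versioned_json(
    list(pattern = result$pattern, init = result$init,
         objective = result$objective, objective_init = result$objective_init,
         traces = result$traces, trajectories = result$trajectories,
         converged = result$converged, settings = result$settings),
    path, "stim_optimization"
  )
}

#' @rdname read_optimization
#' @export
export_pattern_table <- function(result, path) {
  stopifnot(inherits(result, "stim_optimization"))
  readr::write_csv(result$pattern, path)
  invisible(path)
}

#' Write a benchmark table with its run manifest
#'
#' The long-format records go to `path` as CSV; every parameter and seed goes
#' to `paste0(path, ".manifest.json")` so the run is reconstructible.
#'
#' @param benchmark List from [run_benchmark_sweep()].
#' @param path CSV output path.
#' @param manifest Named list of run parameters to record.
#' @export
write_benchmark <- function(benchmark, path, manifest = list()) {
  readr::write_csv(benchmark$records, path)
  readr::write_csv(benchmark$summary, sub("\\.csv$", ".summary.csv", path))
  write_versioned_json(manifest, paste0(path, ".manifest.json"), "run_manifest")
  invisible(path)
}
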