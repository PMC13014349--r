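#' Default run configuration
#'
#' All tunables of the simulation/mapping/optimization pipeline with their
#' default values: population (N = 300 neurons, 411 um square FOV), mapping
#' (25-site grids of half-width 16 um at 8 um steps, 5 um cross-grid
#' redundancy radius, J = 10 targets per trial, 30 um inter-trial spacing),
#' imaging noise SD 0.25, NBFR fit (length scale 6 um, q = 2, inclusion
#' radius 30 um, excitability threshold 0.1), recurrence (connection
#' probability 0.05, transmission sigmoid 0.85 / 3), benchmarking (ensemble
#' size 20, diffuse compactness 0.01, activation threshold 0.5) and the
#' optimizer (step 1 um, 200 iterations, tolerance 1e-6, backtracking on).
#'
#' @return A named list of parameters.
#' @export
default_run_config <- function() {
  list(
    n_neurons = 300, fov_um = 411, noise_sd = 0.25,
    grid_extent = 16, grid_step = 8, min_separation = 5,
    n_targets = 10, min_consecutive_distance = 30,
    length_scale = 6, q_fit = 2, q_truth = 4, inclusion_radius = 30,
    min_evoked = 0.1,
    p_cnx = 0.05, theta0 = 0.85, theta1 = 3,
    ensemble_size = 20, lambda = 0.01, threshold = 0.5,
    step_size = 1, max_iters = 200, tol = 1e-6, backtracking = TRUE,
    n_sims = 20, repetitions = 1, seed = 1
  )
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration file, rejects unknown keys, overlays the values
#' on [default_run_config()] and validates every field against its module's
#' preconditions.
#'
#' @param path JSON file with a subset of the configuration keys, or `NULL`
#'   for pure defaults.
#' @param overrides Named list applied after the file (e.g. CLI flags).
#' @return A validated configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- if (!is.null(path)) jsonlite::read_json(path, simplifyVector = TRUE) else list()
  for (src in list(user, overrides)) {
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown) > 0L) {
      abort(sprintf("Unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
    }
    cfg[names(src)] <- src
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(sprintf("Invalid configuration: %s", msg))
  chk(cfg$n_neurons >= 1, "n_neurons must be >= 1")
  chk(cfg$fov_um > 0, "fov_um must be positive")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$grid_extent > 0 && cfg$grid_step > 0, "grid extent/step must be positive")
  chk(abs(cfg$grid_extent / cfg$grid_step - round(cfg$grid_extent / cfg$grid_step)) < 1e-9,
      "grid_extent must be a multiple of grid_step")
  chk(cfg$min_separation > 0, "min_separation must be positive")
  chk(cfg$n_targets >= 1, "n_targets must be >= 1")
  chk(cfg$length_scale > 0, "length_scale must be positive")
  chk(cfg$q_fit >= 2 && cfg$q_truth >= 2, "basis exponents must be >= 2")
  chk(cfg$inclusion_radius > 0, "inclusion_radius must be positive")
  chk(cfg$p_cnx >= 0 && cfg$p_cnx <= 1, "p_cnx must be in [0, 1]")
  chk(cfg$ensemble_size >= 1 && cfg$ensemble_size <= cfg$n_neurons,
      "ensemble_size must be in [1, n_neurons]")
  chk(cfg$threshold > 0, "threshold must be positive")
  chk(cfg$step_size > 0, "step_size must be positive")
  chk(cfg$repetitions >= 1, "repetitions must be >= 1")
  cfg
}
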