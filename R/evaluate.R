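#' Off-target ratio
#'
#' The number of activated non-target neurons per activated target neuron for
#' one ensemble stimulus. Undefined (returned as `NA`) when no target was
#' activated; undefined ratios are excluded from benchmark means, with their
#' count reported, rather than propagating infinities.
#'
#' @param n_targets_activated,n_nontargets_activated Non-negative counts
#'   (vectorized).
#' @return `n_nontargets_activated / n_targets_activated`, or `NA` where the
#'   denominator is zero.
#' @export
off_target_ratio <- function(n_targets_activated, n_nontargets_activated) {
  if (any(n_targets_activated < 0) || any(n_nontargets_activated < 0)) {
    abort("Activation counts must be non-negative.")
  }
  ifelse(n_targets_activated > 0,
         n_nontargets_activated / n_targets_activated, NA_real_)
}

#' Score somatic versus optimized stimulation for a set of ensembles
#'
#' For each ensemble, stimulates once at the target neurons' somatic
#' centroids and once at the NBFR-optimized sites, and scores both patterns
#' against the ground-truth ORFs. The two conditions are fully paired: same
#' truth, same fitted models, only the pattern differs. Optimization uses the
#' fitted models; scoring always uses ground truth.
#'
#' @param truth `orf_population` ground truth.
#' @param fit `nbfr_fit` fitted on mapping data from the same population.
#' @param ensembles List of neuron-id vectors (or a single vector).
#' @param threshold Activation threshold for scoring (default 0.5).
#' @param ... Passed to [optimize_pattern()].
#' @return A tibble with one row per (ensemble, condition): `ensemble`,
#'   `condition` ("somatic"/"optimized"), `n_targets`, `n_targets_activated`,
#'   `n_nontargets_activated`, `off_target_ratio`.
#' @export
compare_conditions <- function(truth, fit, ensembles, threshold = 0.5, ...) {
  if (!is.list(ensembles)) ensembles <- list(ensembles)
  cent <- orf_centroids(truth)
  rows <- purrr::imap(ensembles, function(targets, e) {
    idx <- match(targets, cent$neuron_id)
    if (anyNA(idx)) abort("Ensemble contains unknown neuron id(s).")
    somatic <- cbind(cent$x_um[idx], cent$y_um[idx])
    opt <- optimize_pattern(fit, targets, ...)
    optimized <- as.matrix(opt$pattern[, c("x_um", "y_um")])
    score <- function(pattern, condition) {
      act <- evaluate_activation(truth, pattern, threshold)
      nt <- sum(act %in% targets)
      nn <- length(act) - nt
      tibble::tibble(
        ensemble = e, condition = condition, n_targets = length(targets),
        n_targets_activated = nt, n_nontargets_activated = nn,
        off_target_ratio = off_target_ratio(nt, nn)
      )
    }
    dplyr::bind_rows(score(somatic, "somatic"), score(optimized, "optimized"))
  })
  dplyr::bind_rows(rows)
}

#' Run one complete simulated mapping-and-optimization experiment
#'
#' The full pipeline on a fresh synthetic population: sample centroids and
#' ground-truth ORFs, design the mapping protocol, simulate noisy mapping
#' responses (optionally with recurrent excitation and/or repetition
#' averaging), fit NBFR, sample target ensembles, and score somatic versus
#' optimized stimulation.
#'
#' @param n_neurons,fov_um,noise_sd Population settings (defaults 300,
#'   411 um, 0.25).
#' @param ensemble_sizes Integer vector; one ensemble is sampled per size.
#' @param lambda Ensemble compactness weight (default 0.01, diffuse).
#' @param gamma Mean recurrent connection strength; `NULL` (default) disables
#'   recurrence during mapping.
#' @param p_cnx Connection probability when recurrence is enabled.
#' @param theta0,theta1 Recurrence transmission sigmoid parameters.
#' @param repetitions Mapping-protocol repetitions averaged before fitting.
#' @param threshold Activation threshold for scoring.
#' @param length_scale,q_fit,inclusion_radius,min_evoked NBFR fit settings.
#' @param seed Integer seed for the whole experiment.
#' @param ... Passed to [optimize_pattern()] via [compare_conditions()].
#' @return The [compare_conditions()] tibble, with columns `ensemble_size`
#'   and `seed` prepended.
#' @export
simulate_experiment <- function(n_neurons = 300, fov_um = 411, noise_sd = 0.25,
                                ensemble_sizes = 20, lambda = 0.01,
                                gamma = NULL, p_cnx = 0.05,
                                theta0 = 0.85, theta1 = 3,
                                repetitions = 1, threshold = 0.5,
                                length_scale = 6, q_fit = 2,
                                inclusion_radius = 30, min_evoked = 0.1,
                                seed = NULL, ...) {
  with_preserved_seed(seed, {
    truth <- simulate_population(n_neurons, fov_um, noise_sd)
    protocol <- design_mapping_protocol(truth$centroids)
    responses <- if (!is.null(gamma)) {
      connectome <- sample_connectivity(n_neurons, p_cnx, gamma)
      if (repetitions > 1) {
        acc <- 0
        for (r in seq_len(repetitions)) {
          acc <- acc + simulate_with_recurrence(truth, connectome, protocol,
                                                theta0, theta1, noise_sd)
        }
        acc / repetitions
      } else {
        simulate_with_recurrence(truth, connectome, protocol, theta0, theta1,
                                 noise_sd)
      }
    } else {
      repetition_averaging(truth, protocol, repetitions, noise_sd)
    }
    fit <- fit_orfs(truth$centroids, protocol$sites, protocol, responses,
                    length_scale = length_scale, q = q_fit,
                    inclusion_radius = inclusion_radius,
                    min_evoked = min_evoked)
    pool <- truth$centroids[fit$neurons$excitable, , drop = FALSE]
    ensembles <- lapply(ensemble_sizes, function(sz) sample_ensemble(pool, sz, lambda))
    out <- compare_conditions(truth, fit, ensembles, threshold, ...)
    out$ensemble_size <- ensemble_sizes[out$ensemble]
    out$seed <- seed %||% NA_integer_
    dplyr::relocate(out, "seed", "ensemble_size")
  })
}

#' Benchmark sweep over a simulation parameter
#'
#' Repeats [simulate_experiment()] `n_sims` times (fresh population each time)
#' for every value of one swept parameter, and aggregates the paired
#' somatic/optimized records: ensembles are averaged within a simulation
#' first, then across simulations. Ensembles with no activated target have an
#' undefined off-target ratio and are excluded from OTR means; their count is
#' reported.
#'
#' @param sweep_var Name of a [simulate_experiment()] argument to sweep, e.g.
#'   `"ensemble_sizes"`, `"n_neurons"`, `"lambda"`, `"gamma"`, `"noise_sd"`,
#'   `"repetitions"`.
#' @param values Vector of values for the swept parameter.
#' @param n_sims Simulations per sweep point.
#' @param seed Base seed; simulation s at sweep point v runs with seed
#'   `seed + (v - 1) * n_sims + s`.
#' @param ... Fixed arguments for [simulate_experiment()].
#' @return A list with `records` (every per-ensemble record, long format) and
#'   `summary` (per sweep value x condition: `mean_otr`, `sd_otr`,
#'   `mean_nontargets`, `sd_nontargets`, `mean_targets_activated`, `n_valid`,
#'   `n_undefined`).
#' @export
run_benchmark_sweep <- function(sweep_var, values, n_sims = 20, seed = 1, ...) {
  fixed <- list(...)
  records <- purrr::imap(values, function(v, vi) {
    purrr::map(seq_len(n_sims), function(s) {
      args <- fixed
      args[[sweep_var]] <- v
      args$seed <- seed + (vi - 1L) * n_sims + s
      rec <- do.call(simulate_experiment, args)
      rec$sweep_var <- sweep_var
      rec$sweep_value <- v
      rec$sim <- s
      rec
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  list(records = records, summary = summarise_benchmark(records))
}

#' Aggregate benchmark records
#'
#' Within-simulation means first (ensembles of one simulated FOV), then
#' across-simulation mean and SD.
#'
#' @param records Long-format record tibble from [run_benchmark_sweep()].
#' @return Summary tibble (one row per sweep value x condition).
#' @export
summarise_benchmark <- function(records) {
  per_sim <- records |>
    dplyr::group_by(.data$sweep_value, .data$condition, .data$sim) |>
    dplyr::summarise(
      otr = mean(.data$off_target_ratio, na.rm = TRUE),
      nontargets = mean(.data$n_nontargets_activated),
      targets_activated = mean(.data$n_targets_activated),
      n_undefined = sum(is.na(.data$off_target_ratio)),
      .groups = "drop"
    )
  per_sim |>
    dplyr::group_by(.data$sweep_value, .data$condition) |>
    dplyr::summarise(
      mean_otr = mean(.data$otr, na.rm = TRUE),
      sd_otr = sd(.data$otr, na.rm = TRUE),
      mean_nontargets = mean(.data$nontargets),
      sd_nontargets = sd(.data$nontargets),
      mean_targets_activated = mean(.data$targets_activated),
      n_valid = sum(!is.nan(.data$otr)),
      n_undefined = sum(.data$n_undefined),
      .groups = "drop"
    )
}

#' Ground-truth recovery error of fitted ORFs
#'
#' Evaluates each neuron's fitted and true ORF on a square grid around its
#' centroid and reports the mean absolute difference -- the parameter-recovery
#' diagnostic used to show that ORF estimates improve with more trials or
#' mapping repetitions.
#'
#' @param truth An `orf_population`.
#' @param fit An `nbfr_fit` on the same population.
#' @param radius_um Grid half-width around each centroid (default 20).
#' @param grid_um Grid spacing (default 1).
#' @return A tibble with `neuron_id` and `mae` plus the population mean as
#'   attribute `mean_mae`.
#' @export
orf_recovery_error <- function(truth, fit, radius_um = 20, grid_um = 1) {
  cent <- orf_centroids(truth)
  offs <- seq(-radius_um, radius_um, by = grid_um)
  grid <- cbind(rep(offs, length(offs)), rep(offs, each = length(offs)))
  mae <- vapply(seq_len(nrow(cent)), function(i) {
    pts <- cbind(grid[, 1L] + cent$x_um[i], grid[, 2L] + cent$y_um[i])
    mean(abs(orf_value(truth, cent$neuron_id[i], pts) -
               orf_value(fit, cent$neuron_id[i], pts)))
  }, 1.0)
  out <- tibble::tibble(neuron_id = cent$neuron_id, mae = mae)
  attr(out, "mean_mae") <- mean(mae)
  out
}
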