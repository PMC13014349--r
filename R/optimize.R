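# Stimulus optimization: reposition 2D holographic targets by analytic
# gradient ascent on the importance-weighted target-minus-non-target
# evoked-activity objective. The objective sums independently over targets,
# so each hologram is optimized on its own axis-free 2D landscape.

# Flat signed/weighted basis table used by the objective and gradient:
# columns center_x, center_y, weight, coef = (+-1) * alpha * weight.
effective_coefs <- function(fit, targets, importance = NULL) {
  stopifnot(inherits(fit, "nbfr_fit"))
  if (length(targets) == 0L) abort("`targets` must name at least one neuron.")
  ids <- fit$neurons$neuron_id
  if (!all(targets %in% ids)) abort("Unknown neuron id(s) in `targets`.")
  alpha <- rep(1, length(ids))
  names(alpha) <- as.character(ids)
  if (!is.null(importance)) {
    if (any(importance < 0)) abort("Importance weights must be >= 0.")
    if (is.null(names(importance))) {
      if (length(importance) != length(ids)) {
        abort("Unnamed `importance` must have one weight per neuron.")
      }
      alpha[] <- importance
    } else {
      alpha[names(importance)] <- importance
    }
  }
  is_target <- ids %in% targets
  # Non-excitable neurons never enter the sums (their fits are unreliable);
  # targets are always kept so that zero-amplitude targets degrade gracefully.
  alpha[!fit$neurons$excitable & !is_target] <- 0
  b <- fit$bases
  sign <- ifelse(b$neuron_id %in% targets, 1, -1)
  coef <- sign * alpha[as.character(b$neuron_id)] * b$weight
  keep <- coef != 0
  tibble::tibble(
    neuron_id = b$neuron_id[keep],
    center_x = b$center_x[keep], center_y = b$center_y[keep],
    coef = unname(coef[keep])
  )
}

#' Neurons entering the optimization under given importance weights
#'
#' Importance scale semantics: a neuron with `alpha = 0` is ignored entirely
#' (useful when its ORF was poorly characterized); `alpha = 1` for all
#' neurons recovers the plain target-minus-non-target objective; a large
#' `alpha` forces a neuron to dominate, effectively requiring its activation
#' (target) or avoidance (non-target).
#'
#' @param fit An `nbfr_fit`.
#' @param targets Vector of target neuron ids (the ensemble Omega).
#' @param importance Optional non-negative weights: either named by neuron id
#'   (unnamed neurons keep weight 1) or a full unnamed length-N vector.
#' @return The vector of neuron ids with nonzero weight in the objective.
#' @export
effective_neurons <- function(fit, targets, importance = NULL) {
  unique(effective_coefs(fit, targets, importance)$neuron_id)
}

#' Stimulation objective: target minus non-target evoked activity
#'
#' Evaluates the importance-weighted objective
#' \eqn{\tilde L(x) = \sum_n \sum_j (-1)^{1[n \notin \Omega]} \alpha_n g_n(x^j)}
#' under the fitted ORF models: the predicted evoked activity summed over
#' target neurons minus that summed over non-target neurons. With all
#' importance weights equal to 1 this is the plain objective.
#'
#' @inheritParams effective_neurons
#' @param pattern J x 2 stimulation pattern (matrix or tibble).
#' @return A scalar.
#' @export
stim_objective <- function(pattern, fit, targets, importance = NULL) {
  pattern <- as_pattern_matrix(pattern)
  cf <- effective_coefs(fit, targets, importance)
  if (nrow(cf) == 0L) return(0)
  p <- fit$params
  d2 <- pairwise_sq_dist(pattern, cbind(cf$center_x, cf$center_y))
  phi <- basis_value_sq(d2, p$length_scale, p$q)
  sum(phi %*% cf$coef)
}

#' Analytic gradient of the stimulation objective
#'
#' For the Gaussian basis (`q = 2`) the gradient with respect to hologram
#' `j` is \eqn{(1/\ell^2) \sum_{n,m} (-1)^{1[n \notin \Omega]} \alpha_n
#' \hat w_{nm} \exp(-\lVert x_{nm} - x^j \rVert^2 / (2\ell^2))
#' (x_{nm} - x^j)}; each hologram's gradient is independent of the other
#' holograms' positions. For `q != 2` no closed form is used and the
#' gradient falls back to central finite differences (with a notice).
#'
#' @inheritParams stim_objective
#' @param fd_step Finite-difference step in microns for the `q != 2`
#'   fallback.
#' @return A J x 2 matrix of objective gradients (ascent directions).
#' @export
stim_gradient <- function(pattern, fit, targets, importance = NULL,
                          fd_step = 1e-4) {
  pattern <- as_pattern_matrix(pattern)
  if (fit$params$q != 2) {
    inform("Analytic gradient requires q = 2; using central finite differences.")
    return(fd_gradient(pattern, fit, targets, importance, fd_step))
  }
  cf <- effective_coefs(fit, targets, importance)
  grad_from_coefs(pattern, cf, fit$params$length_scale)
}

grad_from_coefs <- function(pattern, cf, length_scale) {
  g <- matrix(0, nrow(pattern), 2L)
  if (nrow(cf) == 0L) return(g)
  dx <- outer(cf$center_x, pattern[, 1L], "-") # B x J
  dy <- outer(cf$center_y, pattern[, 2L], "-")
  phi <- exp(-(dx^2 + dy^2) / (2 * length_scale^2))
  w <- cf$coef * phi / length_scale^2
  g <- cbind(colSums(w * dx), colSums(w * dy))
  dimnames(g) <- NULL
  g
}

fd_gradient <- function(pattern, fit, targets, importance, h = 1e-4) {
  g <- matrix(0, nrow(pattern), 2L)
  for (j in seq_len(nrow(pattern))) {
    for (c in 1:2) {
      up <- pattern; up[j, c] <- up[j, c] + h
      dn <- pattern; dn[j, c] <- dn[j, c] - h
      g[j, c] <- (stim_objective(up, fit, targets, importance) -
                    stim_objective(dn, fit, targets, importance)) / (2 * h)
    }
  }
  g
}

#' Optimize a stimulation pattern by gradient ascent
#'
#' Starting from the target neurons' somatic centroids, each hologram is
#' repositioned by gradient ascent on the fitted-ORF objective. Because the
#' objective sums independently over holograms, each target is optimized on
#' its own; with backtracking enabled (default) the step is halved until the
#' objective does not decrease, so the per-target objective trace is
#' monotone non-decreasing and the final pattern is never worse than the
#' somatic initialization under the model.
#'
#' @inheritParams stim_objective
#' @param init Optional J x 2 initialization; defaults to the somatic
#'   centroids of `targets` (in order).
#' @param step_size Initial ascent step (microns per unit gradient).
#' @param max_iters Maximum iterations per hologram (default 200).
#' @param tol Convergence tolerance on the per-iteration objective change.
#' @param backtracking Halve the step until the objective does not decrease.
#' @param max_displacement Optional cap (microns) on each hologram's
#'   displacement from its initialization (default `Inf`, uncapped).
#' @return An object of class `stim_optimization`: list with `pattern`
#'   (tibble `neuron_id`, `x_um`, `y_um`), `init`, `objective`,
#'   `objective_init`, `traces` (per-target objective traces),
#'   `trajectories` (per-target position paths), `converged`, `settings`.
#' @export
optimize_pattern <- function(fit, targets, importance = NULL, init = NULL,
                             step_size = 1, max_iters = 200, tol = 1e-6,
                             backtracking = TRUE, max_displacement = Inf) {
  if (step_size <= 0) abort("`step_size` must be positive.")
  cent <- fit$neurons
  if (is.null(init)) {
    idx <- match(targets, cent$neuron_id)
    if (anyNA(idx)) abort("Unknown neuron id(s) in `targets`.")
    init <- cbind(cent$x_um[idx], cent$y_um[idx])
  }
  init <- as_pattern_matrix(init)
  if (nrow(init) != length(targets)) {
    abort("`init` must provide one hologram per target neuron.")
  }
  cf <- effective_coefs(fit, targets, importance)
  ell <- fit$params$length_scale
  use_analytic <- fit$params$q == 2
  if (!use_analytic) {
    inform("Analytic gradient requires q = 2; optimizing with central finite differences.")
  }
  centers <- cbind(cf$center_x, cf$center_y)

  # local objective/gradient over a neighbourhood of bases (radius 80 um:
  # omitted q = 2 contributions are below exp(-50), i.e. numerically exact)
  neighbourhood <- function(x) {
    if (nrow(cf) == 0L) return(cf[0, ])
    near <- (centers[, 1L] - x[1L])^2 + (centers[, 2L] - x[2L])^2 <= 80^2
    cf[near, , drop = FALSE]
  }
  local_obj <- function(x, nb) {
    if (nrow(nb) == 0L) return(0)
    d2 <- (nb$center_x - x[1L])^2 + (nb$center_y - x[2L])^2
    sum(nb$coef * basis_value_sq(d2, ell, fit$params$q))
  }
  local_grad <- function(x, nb) {
    if (nrow(nb) == 0L) return(c(0, 0))
    dx <- nb$center_x - x[1L]
    dy <- nb$center_y - x[2L]
    if (use_analytic) {
      w <- nb$coef * exp(-(dx^2 + dy^2) / (2 * ell^2)) / ell^2
      c(sum(w * dx), sum(w * dy))
    } else {
      h <- 1e-4
      c((local_obj(x + c(h, 0), nb) - local_obj(x - c(h, 0), nb)) / (2 * h),
        (local_obj(x + c(0, h), nb) - local_obj(x - c(0, h), nb)) / (2 * h))
    }
  }

  J <- nrow(init)
  traces <- vector("list", J)
  trajectories <- vector("list", J)
  converged <- logical(J)
  final <- init
  for (j in seq_len(J)) {
    x <- init[j, ]
    anchor <- x
    nb <- neighbourhood(x)
    obj <- local_obj(x, nb)
    trace <- obj
    path <- matrix(x, 1L)
    for (it in seq_len(max_iters)) {
      if (sqrt(sum((x - anchor)^2)) > 20) { # refresh neighbourhood on drift
        anchor <- x
        nb <- neighbourhood(x)
      }
      g <- local_grad(x, nb)
      if (!all(is.finite(g))) {
        abort(sprintf("Non-finite gradient at hologram %d (position %.2f, %.2f).",
                      j, x[1L], x[2L]))
      }
      eta <- step_size
      repeat {
        prop <- x + eta * g
        if (is.finite(max_displacement)) {
          disp <- prop - init[j, ]
          dn <- sqrt(sum(disp^2))
          if (dn > max_displacement) prop <- init[j, ] + disp * max_displacement / dn
        }
        new_obj <- local_obj(prop, nb)
        if (!backtracking || new_obj >= obj || eta < 1e-8) break
        eta <- eta / 2
      }
      if (backtracking && new_obj < obj) {
        converged[j] <- TRUE # no acceptable ascent step remains
        break
      }
      delta <- new_obj - obj
      x <- prop
      obj <- new_obj
      trace <- c(trace, obj)
      path <- rbind(path, x)
      if (abs(delta) < tol) {
        converged[j] <- TRUE
        break
      }
    }
    traces[[j]] <- trace
    trajectories[[j]] <- path
    final[j, ] <- x
  }

  obj_init <- stim_objective(init, fit, targets, importance)
  obj_final <- stim_objective(final, fit, targets, importance)
  structure(
    list(
      pattern = tibble::tibble(neuron_id = targets,
                               x_um = unname(final[, 1L]),
                               y_um = unname(final[, 2L])),
      init = tibble::tibble(neuron_id = targets,
                            x_um = unname(init[, 1L]),
                            y_um = unname(init[, 2L])),
      objective = obj_final,
      objective_init = obj_init,
      traces = traces,
      trajectories = trajectories,
      converged = converged,
      settings = list(step_size = step_size, max_iters = max_iters, tol = tol,
                      backtracking = backtracking,
                      max_displacement = max_displacement,
                      importance = importance)
    ),
    class = "stim_optimization"
  )
}

#' @export
print.stim_optimization <- function(x, ...) {
  cat(sprintf("<stim_optimization> %d holograms; objective %.4f -> %.4f; %d/%d converged\n",
              nrow(x$pattern), x$objective_init, x$objective,
              sum(x$converged), length(x$converged)))
  invisible(x)
}

#' Rank candidate neurons by expected benefit of stimulus optimization
#'
#' Runs a single-target optimization for every candidate neuron and scores it
#' by the objective improvement over somatic stimulation; neurons whose
#' neighbourhoods make somatic stimulation costly (strong overlapping
#' non-target ORFs) rank first. Test ensembles are then assembled from the
#' top-ranked candidates.
#'
#' @param fit An `nbfr_fit`.
#' @param candidates Candidate neuron ids; defaults to all excitable neurons.
#' @param ensemble_size Neurons per assembled ensemble.
#' @param n_ensembles Number of ensembles to assemble from the ranking.
#' @param ... Passed to [optimize_pattern()].
#' @return A list with `ranking` (tibble `neuron_id`, `improvement`, sorted
#'   descending) and `ensembles` (list of id vectors).
#' @export
select_test_ensembles <- function(fit, candidates = NULL, ensemble_size = 10,
                                  n_ensembles = 1, ...) {
  if (is.null(candidates)) {
    candidates <- fit$neurons$neuron_id[fit$neurons$excitable]
  }
  if (length(candidates) == 0L) abort("No excitable candidate neurons.")
  improvement <- vapply(candidates, function(id) {
    opt <- optimize_pattern(fit, id, ...)
    opt$objective - opt$objective_init
  }, 1.0)
  ranking <- tibble::tibble(neuron_id = candidates, improvement = improvement) |>
    dplyr::arrange(dplyr::desc(.data$improvement))
  n_avail <- floor(nrow(ranking) / ensemble_size)
  n_take <- min(n_ensembles, n_avail)
  ensembles <- lapply(seq_len(n_take), function(i) {
    ranking$neuron_id[((i - 1L) * ensemble_size + 1L):(i * ensemble_size)]
  })
  list(ranking = ranking, ensembles = ensembles)
}
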