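# Builders for small, fully specified scenes and independent oracles.
# Everything is constructed in code; no fixture files.

# An nbfr_fit with hand-chosen bases and weights.
make_manual_fit <- function(neurons, bases, length_scale = 6, q = 2,
                            inclusion_radius = 30, min_evoked = 0.1) {
  neurons <- tibble::as_tibble(neurons)
  bases <- tibble::as_tibble(bases)
  if (!"site_id" %in% names(bases)) bases$site_id <- seq_len(nrow(bases))
  neurons$n_bases <- as.integer(table(factor(bases$neuron_id,
                                             levels = neurons$neuron_id)))
  neurons$noise_sd <- 0
  fit <- structure(
    list(neurons = neurons,
         bases = bases[, c("neuron_id", "site_id", "center_x", "center_y", "weight")],
         params = list(length_scale = length_scale, q = q,
                       inclusion_radius = inclusion_radius,
                       min_evoked = min_evoked, trial_margin = 25)),
    class = "nbfr_fit"
  )
  flag_excitable(fit, min_evoked)
}

# A ground-truth orf_population with hand-chosen mixture components.
make_manual_truth <- function(centroids, bases, q = 4, fov_um = 411,
                              noise_sd = 0.25) {
  structure(
    list(centroids = tibble::as_tibble(centroids),
         bases = tibble::as_tibble(bases),
         q = q, fov_um = fov_um, noise_sd = noise_sd),
    class = "orf_population"
  )
}

# A random small scene for optimizer/gradient tests: a handful of neurons,
# each with a few bases near its centroid, the first `n_targets` are targets.
random_scene <- function(seed, n_neurons = 6, n_targets = 2, length_scale = 6,
                         q = 2, span = 60) {
  set.seed(seed)
  neurons <- tibble::tibble(
    neuron_id = seq_len(n_neurons),
    x_um = runif(n_neurons, 0, span),
    y_um = runif(n_neurons, 0, span)
  )
  nb <- sample(2:5, n_neurons, replace = TRUE)
  bases <- tibble::tibble(
    neuron_id = rep(neurons$neuron_id, nb),
    center_x = rep(neurons$x_um, nb) + runif(sum(nb), -10, 10),
    center_y = rep(neurons$y_um, nb) + runif(sum(nb), -10, 10),
    weight = runif(sum(nb), 0.1, 1)
  )
  fit <- make_manual_fit(neurons, bases, length_scale = length_scale, q = q)
  list(fit = fit, targets = seq_len(n_targets))
}

# Triple-loop reference for the importance-weighted objective.
brute_objective <- function(pattern, fit, targets, importance = NULL) {
  pattern <- as.matrix(pattern)
  p <- fit$params
  total <- 0
  for (n in seq_len(nrow(fit$neurons))) {
    id <- fit$neurons$neuron_id[n]
    alpha <- 1
    if (!is.null(importance) && as.character(id) %in% names(importance)) {
      alpha <- importance[[as.character(id)]]
    }
    if (!fit$neurons$excitable[n] && !(id %in% targets)) alpha <- 0
    sgn <- if (id %in% targets) 1 else -1
    b <- fit$bases[fit$bases$neuron_id == id, ]
    for (j in seq_len(nrow(pattern))) {
      g <- 0
      if (nrow(b) > 0) {
        for (m in seq_len(nrow(b))) {
          d <- sqrt((b$center_x[m] - pattern[j, 1])^2 +
                      (b$center_y[m] - pattern[j, 2])^2)
          g <- g + b$weight[m] * exp(-d^p$q / (2 * p$length_scale^p$q))
        }
      }
      total <- total + sgn * alpha * g
    }
  }
  total
}

# Exhaustive active-set oracle for non-negative least squares: solve plain
# least squares on every subset of columns, keep the best feasible solution.
enumerate_nnls_objective <- function(design, y) {
  M <- ncol(design)
  best <- sum(y^2) # empty subset: all weights zero
  for (size in seq_len(M)) {
    for (subset in utils::combn(M, size, simplify = FALSE)) {
      A <- design[, subset, drop = FALSE]
      w <- tryCatch(qr.coef(qr(A), y), error = function(e) NULL)
      if (is.null(w) || anyNA(w) || any(w < 0)) next
      best <- min(best, sum((y - A %*% w)^2))
    }
  }
  best
}

# Checker for protocol invariants: coverage (each site exactly once) and the
# inter-trial spacing constraint (violating consecutive pairs must not exceed
# the logged relaxation count).
check_protocol <- function(protocol, retained_sites) {
  trials <- protocol$trials
  cover <- sort(trials$site_id)
  expect_identical(cover, sort(retained_sites$site_id))
  expect_true(all(table(trials$site_id) == 1))
  byt <- split(trials, trials$trial)
  dmin <- protocol$params$min_consecutive_distance
  violations <- 0L
  for (k in seq_len(length(byt) - 1L)) {
    a <- byt[[k]]; b <- byt[[k + 1L]]
    d2 <- outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2
    if (any(d2 < dmin^2)) violations <- violations + 1L
  }
  expect_lte(violations, protocol$n_relaxed)
  invisible(violations)
}

# Access to the internal noiseless drive matrix for oracle comparisons.
orf_drive_matrix_pub <- function(...) nbfr:::orf_drive_matrix(...)
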