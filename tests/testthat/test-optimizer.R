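test_that("the objective implements the signed importance-weighted sum", {
  sc <- random_scene(301, n_neurons = 6, n_targets = 2)
  pattern <- matrix(runif(8, 0, 60), ncol = 2)

  # alpha = 0 for everyone: the objective vanishes
  zero_alpha <- setNames(rep(0, 6), as.character(1:6))
  expect_equal(stim_objective(pattern, sc$fit, sc$targets, zero_alpha), 0)

  # one target neuron, single basis of weight w, hologram on the center
  lone <- make_manual_fit(
    tibble::tibble(neuron_id = 1L, x_um = 0, y_um = 0),
    tibble::tibble(neuron_id = 1L, center_x = 0, center_y = 0, weight = 0.9)
  )
  expect_equal(stim_objective(rbind(c(0, 0)), lone, 1L), 0.9)

  # random scene against the brute-force triple sum with sign bookkeeping
  expect_equal(stim_objective(pattern, sc$fit, sc$targets),
               brute_objective(pattern, sc$fit, sc$targets), tolerance = 1e-10)
  imp <- setNames(runif(6, 0, 2), as.character(1:6))
  expect_equal(stim_objective(pattern, sc$fit, sc$targets, imp),
               brute_objective(pattern, sc$fit, sc$targets, imp),
               tolerance = 1e-10)
  expect_error(stim_objective(pattern, sc$fit, sc$targets,
                              setNames(-1, "1")), ">= 0")
})

test_that("the analytic gradient is exact: symmetry and finite differences", {
  # hologram exactly on the only basis center: zero gradient
  lone <- make_manual_fit(
    tibble::tibble(neuron_id = 1L, x_um = 0, y_um = 0),
    tibble::tibble(neuron_id = 1L, center_x = 0, center_y = 0, weight = 1)
  )
  expect_equal(stim_gradient(rbind(c(0, 0)), lone, 1L), matrix(0, 1, 2))

  # two equal-weight non-target bases mirror-symmetric about the hologram:
  # the perpendicular component cancels, the resultant points away from them
  sym <- make_manual_fit(
    tibble::tibble(neuron_id = 1:3, x_um = c(-50, 8, 8), y_um = c(0, 5, -5)),
    tibble::tibble(neuron_id = 1:3,
                   center_x = c(-50, 8, 8), center_y = c(0, 5, -5),
                   weight = c(1, 0.6, 0.6))
  )
  g <- stim_gradient(rbind(c(0, 0)), sym, 1L)
  expect_equal(g[1, 2], 0, tolerance = 1e-12) # y-components cancel
  expect_lt(g[1, 1], 0) # pushed along -x, away from the non-target pair

  # randomized scenes against central finite differences
  for (s in 1:20) {
    sc <- random_scene(400 + s, n_neurons = 5, n_targets = 2)
    pattern <- matrix(runif(4 * 2, 10, 50), ncol = 2)
    ga <- stim_gradient(pattern, sc$fit, sc$targets)
    gn <- nbfr:::fd_gradient(pattern, sc$fit, sc$targets, NULL, 1e-4)
    expect_lt(max(abs(ga - gn)) / max(abs(ga)), 1e-5)
  }
})

test_that("q != 2 models fall back to finite differences with a notice", {
  sc <- random_scene(555, n_neurons = 4, n_targets = 1, q = 4)
  pattern <- matrix(runif(4, 10, 50), ncol = 2)
  expect_message(g <- stim_gradient(pattern, sc$fit, sc$targets), "finite differences")
  gn <- nbfr:::fd_gradient(pattern, sc$fit, sc$targets, NULL, 1e-4)
  expect_equal(g, gn)
})

test_that("gradient ascent repositions holograms toward the constrained optimum", {
  # zero-weight model: nothing to ascend, initialization returned unchanged
  dead <- make_manual_fit(
    tibble::tibble(neuron_id = 1L, x_um = 10, y_um = 10),
    tibble::tibble(neuron_id = 1L, center_x = 10, center_y = 10, weight = 0)
  )
  opt0 <- optimize_pattern(dead, 1L)
  expect_equal(as.matrix(opt0$pattern[, c("x_um", "y_um")]),
               as.matrix(opt0$init[, c("x_um", "y_um")]), ignore_attr = TRUE)
  expect_true(all(opt0$converged))
  expect_equal(length(opt0$traces[[1]]), 2L) # converged after one iteration

  # one target and one overlapping non-target 15 um apart: the optimized site
  # moves along the line away from the non-target; the 1D closed-form
  # maximizer along that axis is the oracle
  pair <- make_manual_fit(
    tibble::tibble(neuron_id = 1:2, x_um = c(0, 15), y_um = c(0, 0)),
    tibble::tibble(neuron_id = 1:2, center_x = c(0, 15), center_y = c(0, 0),
                   weight = c(1, 1))
  )
  opt <- optimize_pattern(pair, 1L)
  f1d <- function(x) exp(-x^2 / 72) - exp(-(x - 15)^2 / 72)
  oracle <- optimize(f1d, c(-40, 14), maximum = TRUE)
  expect_lt(opt$pattern$x_um, -0.5) # displaced away from the non-target
  expect_equal(opt$pattern$y_um, 0, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(opt$pattern$x_um, oracle$maximum, tolerance = 0.1,
               ignore_attr = TRUE)
  expect_equal(opt$objective, oracle$objective, tolerance = 1e-4)
  expect_gt(opt$objective, opt$objective_init)
})

test_that("three-target scenes reach the per-target grid-search maximum", {
  # three targets, each shadowed by a nearby weaker non-target (the classic
  # ensemble-with-interleaved-neighbours configuration); the oracle is an
  # independent 1-um grid search per hologram
  cent <- tibble::tibble(
    neuron_id = 1:6,
    x_um = c(40, 100, 70, 52, 100, 62), y_um = c(40, 40, 90, 40, 52, 82)
  )
  fit3 <- make_manual_fit(cent, tibble::tibble(
    neuron_id = rep(1:6, each = 2),
    center_x = rep(cent$x_um, each = 2) + c(0, 3, 0, -3, 0, 2, 0, 3, 0, -2, 0, 2),
    center_y = rep(cent$y_um, each = 2) + c(0, 2, 0, 2, 0, -3, 0, -2, 0, 2, 0, 1),
    weight = rep(c(1, 0.5), 6)
  ))
  opt <- optimize_pattern(fit3, 1:3)
  grid_max_for <- function(j) {
    init <- c(fit3$neurons$x_um[j], fit3$neurons$y_um[j])
    gx <- seq(init[1] - 20, init[1] + 20, by = 1)
    gy <- seq(init[2] - 20, init[2] + 20, by = 1)
    pts <- cbind(rep(gx, length(gy)), rep(gy, each = length(gx)))
    vals <- vapply(seq_len(nrow(pts)), function(i) {
      brute_objective(pts[i, , drop = FALSE], fit3, 1:3)
    }, 1.0)
    max(vals)
  }
  grid_total <- sum(vapply(1:3, grid_max_for, 1.0))
  expect_gte(opt$objective, grid_total - 1e-3)
})

test_that("each hologram's optimum is independent of the other holograms", {
  # Eq-separability: moving the other holograms' initializations far away
  # leaves hologram 1's optimized position unchanged
  sc <- random_scene(808, n_neurons = 7, n_targets = 3)
  base <- optimize_pattern(sc$fit, sc$targets)
  shifted_init <- as.matrix(base$init[, c("x_um", "y_um")])
  shifted_init[2, ] <- shifted_init[2, ] + c(13, -7)
  shifted_init[3, ] <- shifted_init[3, ] + c(-9, 11)
  moved <- optimize_pattern(sc$fit, sc$targets, init = shifted_init)
  expect_equal(as.numeric(moved$pattern[1, c("x_um", "y_um")]),
               as.numeric(base$pattern[1, c("x_um", "y_um")]),
               tolerance = 1e-12)
})

test_that("backtracking ascent is monotone and never worse than somatic", {
  for (s in 1:8) {
    sc <- random_scene(900 + s, n_neurons = 8, n_targets = 3)
    opt <- optimize_pattern(sc$fit, sc$targets)
    for (tr in opt$traces) {
      expect_true(all(diff(tr) >= -1e-12))
    }
    expect_gte(opt$objective, opt$objective_init - 1e-9)
  }
})

test_that("importance weights reshape the optimization as documented", {
  sc <- random_scene(1001, n_neurons = 6, n_targets = 2)
  pattern <- matrix(runif(6, 10, 50), ncol = 2)

  # alpha = 0 for all non-targets: objective equals the target-only sum
  imp <- setNames(rep(0, 6), as.character(1:6))
  imp[as.character(sc$targets)] <- 1
  target_only <- sum(vapply(sc$targets, function(id) {
    b <- sc$fit$bases[sc$fit$bases$neuron_id == id, ]
    sum(vapply(seq_len(nrow(pattern)), function(j) {
      d2 <- (b$center_x - pattern[j, 1])^2 + (b$center_y - pattern[j, 2])^2
      sum(b$weight * exp(-d2 / 72))
    }, 1.0))
  }, 1.0))
  expect_equal(stim_objective(pattern, sc$fit, sc$targets, imp), target_only,
               tolerance = 1e-10)
  expect_setequal(effective_neurons(sc$fit, sc$targets, imp), sc$targets)

  # all-ones importance is the unweighted objective
  ones <- setNames(rep(1, 6), as.character(1:6))
  expect_identical(optimize_pattern(sc$fit, sc$targets, importance = ones)$pattern,
                   optimize_pattern(sc$fit, sc$targets)$pattern)

  # raising an overlapping non-target's importance strictly lowers the
  # attainable objective
  pair <- make_manual_fit(
    tibble::tibble(neuron_id = 1:2, x_um = c(0, 12), y_um = c(0, 0)),
    tibble::tibble(neuron_id = 1:2, center_x = c(0, 12), center_y = c(0, 0),
                   weight = c(1, 0.8))
  )
  base <- optimize_pattern(pair, 1L)$objective
  heavy <- optimize_pattern(pair, 1L, importance = c("2" = 2))$objective
  expect_lt(heavy, base)
})

test_that("a target ringed by strong non-targets is pushed out of every ORF", {
  # ring with a gap (full symmetry would pin the gradient to zero); the
  # high-weight neighbours dominate the weakly responsive target
  ring_angles <- seq(0, 1.5 * pi, length.out = 5)
  ring <- make_manual_fit(
    tibble::tibble(neuron_id = 1:6,
                   x_um = c(0, 6 * cos(ring_angles)),
                   y_um = c(0, 6 * sin(ring_angles))),
    tibble::tibble(neuron_id = 1:6,
                   center_x = c(0, 6 * cos(ring_angles)),
                   center_y = c(0, 6 * sin(ring_angles)),
                   weight = c(0.2, rep(3, 5)))
  )
  opt <- optimize_pattern(ring, 1L, max_iters = 400)
  # the hologram escapes the ring; the model reports ~zero target activation,
  # allowing callers to detect and veto (abort stimulation)
  target_act <- predict_response(ring, as.matrix(opt$pattern[, c("x_um", "y_um")]))
  expect_lt(target_act$response[target_act$neuron_id == 1], 0.05)
  expect_gt(sqrt(opt$pattern$x_um^2 + opt$pattern$y_um^2), 6)
})

test_that("candidate ranking by optimization benefit matches re-evaluation", {
  # an isolated neuron gains nothing; a neuron shadowed by a strong
  # non-target gains the most
  trio <- make_manual_fit(
    tibble::tibble(neuron_id = 1:3, x_um = c(0, 200, 212), y_um = c(0, 0, 0)),
    tibble::tibble(neuron_id = 1:3, center_x = c(0, 200, 212),
                   center_y = c(0, 0, 0), weight = c(1, 1, 1.5))
  )
  sel <- select_test_ensembles(trio, ensemble_size = 1, n_ensembles = 3)
  expect_equal(sel$ranking$neuron_id[3], 1L) # isolated neuron ranked last
  expect_lt(sel$ranking$improvement[3], 1e-6)
  expect_gt(sel$ranking$improvement[1], 0)

  # ranking agrees with brute-force re-evaluation of every candidate
  sc <- random_scene(1203, n_neurons = 8, n_targets = 1)
  sel2 <- select_test_ensembles(sc$fit, ensemble_size = 2, n_ensembles = 2)
  redo <- vapply(sel2$ranking$neuron_id, function(id) {
    o <- optimize_pattern(sc$fit, id)
    o$objective - o$objective_init
  }, 1.0)
  expect_equal(sel2$ranking$improvement, redo, tolerance = 1e-10)
  expect_true(all(diff(sel2$ranking$improvement) <= 1e-12))
  expect_equal(lengths(sel2$ensembles), c(2L, 2L))
})
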