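test_that("populations are uniform in the FOV and seed-reproducible", {
  p1 <- sample_population(1, seed = 1)
  expect_true(p1$x_um >= 0 && p1$x_um <= 411 && p1$y_um >= 0 && p1$y_um <= 411)

  p <- sample_population(300, seed = 2)
  expect_true(all(p$x_um >= 0 & p$x_um <= 411 & p$y_um >= 0 & p$y_um <= 411))
  expect_identical(p, sample_population(300, seed = 2))
  expect_error(sample_population(0), ">= 1")

  # quadrant uniformity (chi-square on a larger draw)
  big <- sample_population(4000, seed = 3)
  quad <- table(big$x_um > 205.5, big$y_um > 205.5)
  expect_gt(stats::chisq.test(quad)$p.value, 0.001)
})

test_that("ground-truth ORFs are unit-peak mixtures with realistic spatial reach", {
  # a single on-soma component peaks at exactly 1 on the centroid
  cent <- tibble::tibble(neuron_id = 1L, x_um = 50, y_um = 50)
  t1 <- sample_ground_truth_orfs(cent, n_bases_range = c(1, 1),
                                 offset_range = 0, seed = 4)
  expect_equal(orf_value(t1, 1L, rbind(c(50, 50))), 1, tolerance = 1e-9)

  # normalization contract: the grid peak never exceeds 1, sits within grid
  # discretization error of 1, and refining the best grid point by continuous
  # maximization recovers a peak of exactly 1
  truth <- simulate_population(40, fov_um = 150, seed = 5)
  offs <- seq(-14, 14, by = 1)
  grid <- cbind(rep(offs, length(offs)), rep(offs, each = length(offs)))
  peaks <- vapply(seq_len(40), function(i) {
    pts <- cbind(grid[, 1] + truth$centroids$x_um[i],
                 grid[, 2] + truth$centroids$y_um[i])
    vals <- orf_value(truth, i, pts)
    ref <- stats::optim(pts[which.max(vals), ],
                        function(x) -orf_value(truth, i, rbind(x)),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12))
    expect_equal(-ref$value, 1, tolerance = 1e-6)
    max(vals)
  }, 1.0)
  expect_true(all(peaks <= 1 + 1e-9))
  expect_true(all(peaks >= 1 - 0.01))

  # some neurons in a default population respond strongly (>= 0.5) at sites
  # more than 15 um from their centroid -- the off-target phenomenology
  big <- simulate_population(300, seed = 6)
  far_resp <- vapply(seq_len(300), function(i) {
    ang <- seq(0, 2 * pi, length.out = 25)
    pts <- cbind(big$centroids$x_um[i] + 15.5 * cos(ang),
                 big$centroids$y_um[i] + 15.5 * sin(ang))
    max(orf_value(big, i, pts))
  }, 1.0)
  expect_gt(sum(far_resp >= 0.5), 5)
  expect_lt(sum(far_resp >= 0.5), 300) # but not universal
})

test_that("simulated responses are ORF drive plus calibrated Gaussian noise", {
  truth <- simulate_population(25, fov_um = 120, seed = 7)
  protocol <- design_mapping_protocol(truth$centroids, seed = 8)

  # noiseless responses equal the brute-force drive sums
  y0 <- simulate_responses(truth, protocol, noise_sd = 0)
  patterns <- lapply(split(protocol$trials, protocol$trials$trial),
                     function(tr) cbind(tr$x_um, tr$y_um))
  for (k in c(1, 5, length(patterns))) {
    for (i in c(1, 13, 25)) {
      expect_lt(abs(y0[k, i] - sum(orf_value(truth, i, patterns[[k]]))), 1e-8)
    }
  }

  # Monte-Carlo moment check: per-neuron sample SD ~= 0.25 within 3 SE
  pat <- list(rbind(c(60, 60)))
  reps <- vapply(1:4000, function(r) simulate_responses(truth, pat, 0.25)[1, 1],
                 1.0)
  se <- 0.25 / sqrt(2 * (4000 - 1))
  expect_lt(abs(sd(reps) - 0.25), 3 * se)

  # a pattern far outside every ORF yields pure noise around zero
  far <- simulate_responses(truth, list(rbind(c(5000, 5000))), 0.25, seed = 9)
  expect_lt(abs(mean(far)), 0.25)
  expect_equal(max(abs(far - mean(far))) > 0, TRUE)
  expect_equal(orf_drive_matrix_pub(truth, list(rbind(c(5000, 5000)))),
               matrix(0, 1, 25), ignore_attr = TRUE)

  # determinism end-to-end
  expect_identical(simulate_responses(truth, protocol, seed = 10),
                   simulate_responses(truth, protocol, seed = 10))
})

test_that("ensemble sampling follows the distance-weighted law", {
  cent <- sample_population(40, fov_um = 200, seed = 11)
  expect_length(sample_ensemble(cent, 1, seed = 12), 1L)
  expect_error(sample_ensemble(cent, 41), "exceeds")

  # lambda -> 0: remaining members uniform (chi-square over many draws)
  draws <- unlist(lapply(1:600, function(s) {
    sample_ensemble(cent, 5, lambda = 1e-9, seed = s)[-1]
  }))
  tab <- table(factor(draws, levels = cent$neuron_id))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)

  # extreme lambda: members are exactly the nearest neighbors of the center
  for (s in 1:10) {
    ens <- sample_ensemble(cent, 4, lambda = 10, seed = 40 + s)
    ctr <- match(ens[1], cent$neuron_id)
    d <- sqrt((cent$x_um - cent$x_um[ctr])^2 + (cent$y_um - cent$y_um[ctr])^2)
    nearest <- cent$neuron_id[order(d)][2:4]
    expect_setequal(ens[-1], nearest)
  }
})

test_that("connectivity is zero-inflated exponential with zero diagonal", {
  expect_true(all(sample_connectivity(30, p_cnx = 0, gamma = 1, seed = 13) == 0))

  r_full <- sample_connectivity(60, p_cnx = 1, gamma = 1, seed = 14)
  expect_true(all(diag(r_full) == 0))
  off <- r_full[row(r_full) != col(r_full)]
  expect_equal(mean(off), 1, tolerance = 0.05)
  expect_gt(stats::ks.test(off, "pexp", 1)$p.value, 0.001)

  r <- sample_connectivity(300, p_cnx = 0.05, gamma = 0.01, seed = 15)
  n_off <- 300 * 299
  frac <- sum(r != 0) / n_off
  se <- sqrt(0.05 * 0.95 / n_off)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("recurrence reduces to the plain simulator and scales with gamma", {
  truth <- simulate_population(25, fov_um = 120, seed = 16)
  protocol <- design_mapping_protocol(truth$centroids, seed = 17)

  # zero connectome: byte-identical to simulate_responses under a shared seed
  zero <- matrix(0, 25, 25)
  expect_equal(simulate_with_recurrence(truth, zero, protocol, seed = 18),
               simulate_responses(truth, protocol, seed = 18))

  # zero photostimulation: per-trial spike probability is plogis(-3)
  far <- lapply(1:400, function(k) rbind(c(5000, 5000)))
  dense <- matrix(1, 25, 25); diag(dense) <- 0
  y <- simulate_with_recurrence(truth, dense, far, noise_sd = 0, seed = 19)
  # each response = number of presynaptic spikes among 24 partners
  spike_rate <- mean(y) / 24
  expect_equal(spike_rate, plogis(-3), tolerance = 0.1)

  # mean contaminating input scales ~1000x between gamma = 1 and 0.001
  conn_lo <- sample_connectivity(25, 0.2, gamma = 0.001, seed = 20)
  conn_hi <- sample_connectivity(25, 0.2, gamma = 1, seed = 20)
  drive <- orf_drive_matrix_pub(truth, protocol)
  rec_lo <- simulate_with_recurrence(truth, conn_lo, protocol, noise_sd = 0,
                                     seed = 21) - drive
  rec_hi <- simulate_with_recurrence(truth, conn_hi, protocol, noise_sd = 0,
                                     seed = 21) - drive
  expect_equal(mean(rec_hi) / mean(rec_lo), 1000, tolerance = 1e-6)
})

test_that("activation is thresholded noiseless drive", {
  truth <- simulate_population(30, fov_um = 130, seed = 22)
  # stimulating a neuron's ORF peak activates it (peak = 1 >= 0.5)
  b <- truth$bases[truth$bases$neuron_id == 1, ]
  peak_at <- b[which.max(b$weight), c("center_x", "center_y")]
  offs <- expand.grid(dx = seq(-6, 6, 0.5), dy = seq(-6, 6, 0.5))
  pts <- cbind(peak_at$center_x + offs$dx, peak_at$center_y + offs$dy)
  peak_pt <- pts[which.max(orf_value(truth, 1L, pts)), , drop = FALSE]
  expect_true(1L %in% evaluate_activation(truth, peak_pt, 0.5))

  # empty pattern: nothing is activated
  expect_length(evaluate_activation(truth, matrix(numeric(), 0, 2)), 0L)

  # random pattern against the brute-force thresholding oracle
  pat <- matrix(runif(10, 0, 130), ncol = 2)
  act <- evaluate_activation(truth, pat, 0.5)
  oracle <- which(vapply(seq_len(30), function(i) {
    sum(orf_value(truth, i, pat)) >= 0.5
  }, TRUE))
  expect_setequal(act, oracle)
})
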