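# Internal helpers shared across modules. Coordinates are continuous microns
# in a single field-of-view frame, origin at the lower-left corner.

# Coerce a pattern (J stimulation targets) to a J x 2 numeric matrix with
# columns x_um, y_um. Accepts matrices, data frames and length-2 vectors.
as_pattern_matrix <- function(pattern) {
  if (is.numeric(pattern) && is.null(dim(pattern)) && length(pattern) == 2L) {
    pattern <- matrix(pattern, ncol = 2L)
  }
  if (is.data.frame(pattern)) {
    cols <- if (all(c("x_um", "y_um") %in% names(pattern))) c("x_um", "y_um") else 1:2
    pattern <- as.matrix(pattern[, cols, drop = FALSE])
  }
  if (!is.matrix(pattern) || ncol(pattern) != 2L) {
    abort("A stimulation pattern must be a J x 2 set of (x_um, y_um) coordinates.")
  }
  storage.mode(pattern) <- "double"
  if (nrow(pattern) < 1L) abort("A stimulation pattern needs at least one target.")
  if (!all(is.finite(pattern))) abort("Stimulation-target coordinates must be finite.")
  colnames(pattern) <- c("x_um", "y_um")
  pattern
}

# Warn (not error) when targets fall outside the declared FOV bounds.
check_pattern_fov <- function(pattern, fov_um) {
  if (is.null(fov_um)) return(invisible(pattern))
  out <- pattern[, 1L] < 0 | pattern[, 1L] > fov_um | pattern[, 2L] < 0 | pattern[, 2L] > fov_um
  if (any(out)) {
    warn(sprintf("%d stimulation target(s) lie outside the %g um FOV.", sum(out), fov_um))
  }
  invisible(pattern)
}

# Squared Euclidean distances between rows of a (n x 2) and rows of b (m x 2).
pairwise_sq_dist <- function(a, b) {
  out <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  dimnames(out) <- NULL
  out
}

validate_centroids <- function(centroids) {
  if (!is.data.frame(centroids) || !all(c("neuron_id", "x_um", "y_um") %in% names(centroids))) {
    abort("`centroids` must have columns neuron_id, x_um, y_um.")
  }
  if (anyDuplicated(centroids$neuron_id)) {
    dup <- unique(centroids$neuron_id[duplicated(centroids$neuron_id)])
    abort(sprintf("Duplicate neuron_id(s): %s", paste(dup, collapse = ", ")))
  }
  if (!all(is.finite(centroids$x_um)) || !all(is.finite(centroids$y_um))) {
    abort("Centroid coordinates must be finite numbers.")
  }
  tibble::as_tibble(centroids)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Used by every seeded entry point so that seeded
# calls are reproducible without disturbing the session RNG.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
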