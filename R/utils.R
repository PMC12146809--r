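# Internal helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive a stream of child seeds from one seed (kept below 2^31).
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Voxel-center coordinates (mm) along one axis: centers of cells 1..n.
axisCenters <- function(n, d) (seq_len(n) - 0.5) * d

# Logical mask of voxels whose center lies inside an ellipsoid.
# center and semi are length-3 in mm; sphere = equal semi-axes.
ellipsoidMask <- function(dims, spacing, center, semi) {
  if (length(semi) == 1) semi <- rep(semi, 3)
  u <- (axisCenters(dims[1], spacing[1]) - center[1]) / semi[1]
  v <- (axisCenters(dims[2], spacing[2]) - center[2]) / semi[2]
  w <- (axisCenters(dims[3], spacing[3]) - center[3]) / semi[3]
  q <- outer(outer(u^2, v^2, "+"), w^2, "+")
  q <= 1
}

# Axis-aligned box mask (edges in mm); voxel centers strictly inside.
boxMask <- function(dims, spacing, lo, hi) {
  inAxis <- function(n, d, a, b) {
    x <- axisCenters(n, d)
    x > a & x < b
  }
  u <- inAxis(dims[1], spacing[1], lo[1], hi[1])
  v <- inAxis(dims[2], spacing[2], lo[2], hi[2])
  w <- inAxis(dims[3], spacing[3], lo[3], hi[3])
  outer(outer(u, v, "&"), w, "&")
}

# Separable Gaussian blur with the given FWHM (mm); replicate-padded edges.
gaussianBlur3d <- function(arr, spacing, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  blur1 <- function(m, d) {
    s <- sigma / d
    hw <- max(1L, ceiling(3 * s))
    k <- exp(-((-hw:hw)^2) / (2 * s^2)); k <- k / sum(k)
    n <- nrow(m)
    idx <- outer(seq_len(n), -hw:hw, "+")
    idx[idx < 1] <- 1; idx[idx > n] <- n
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  d <- dim(arr)
  a <- array(blur1(matrix(arr, d[1]), spacing[1]), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(blur1(matrix(a, d[2]), spacing[2]), d[c(2, 1, 3)])
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 1, 2))
  a <- array(blur1(matrix(a, d[3]), spacing[3]), d[c(3, 1, 2)])
  aperm(a, c(2, 3, 1))
}
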