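# Brute-force oracles, independent of the implementation paths they check.

# All-pairs Harrell concordance by explicit double loop.
oracleCindex <- function(score, time, event) {
  conc <- pairs <- 0
  n <- length(score)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!usable) next
    pairs <- pairs + 1
    if (score[i] > score[j]) conc <- conc + 1
    else if (score[i] == score[j]) conc <- conc + 0.5
  }
  conc / pairs
}

# Two-group log-rank chi-square from explicit hypergeometric tables.
oracleLogrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  (O - E)^2 / V
}

# Efron partial log-likelihood for one covariate, for grid-search oracle.
oracleEfronLoglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    m <- length(D)
    sumR <- sum(exp(beta * x[R]))
    sumD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D]) -
      sum(vapply(seq_len(m) - 1,
                 function(l) log(sumR - l / m * sumD), numeric(1)))
  }
  ll
}

# Maximize the Efron partial likelihood on a fine grid, then refine.
oracleCoxGrid <- function(time, event, x, lim = c(-4, 4)) {
  grid <- seq(lim[1], lim[2], by = 0.001)
  ll <- vapply(grid, oracleEfronLoglik, numeric(1), time, event, x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.002, b0 + 0.002, by = 1e-5)
  llf <- vapply(fine, oracleEfronLoglik, numeric(1), time, event, x)
  fine[which.max(llf)]
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration.
oracleFisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  supp <- max(0, k - n2):min(k, m)
  probs <- dhyper(supp, m, n2, k)
  p0 <- dhyper(a, m, n2, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Connected components of a 3-D mask via igraph on the voxel adjacency graph.
oracleComponents <- function(mask, connectivity = 26) {
  idx <- which(mask)
  if (!length(idx)) return(array(0L, dim(mask)))
  co <- arrayInd(idx, dim(mask))
  edges <- integer(0)
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i >= j) next
    dd <- abs(co[i, ] - co[j, ])
    adjacent <- switch(as.character(connectivity),
      "6"  = sum(dd) == 1,
      "18" = max(dd) == 1 && sum(dd) <= 2,
      "26" = max(dd) == 1)
    if (adjacent) edges <- c(edges, i, j)
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  out <- array(0L, dim(mask))
  # relabel to first-voxel lexicographic order to match the implementation
  relabel <- match(memb, unique(memb))
  out[idx] <- relabel
  out
}

# Voxel-center count inside a sphere, by exhaustive enumeration.
oracleSphereCount <- function(dims, spacing, center, radius) {
  cnt <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      p <- (c(i, j, k) - 0.5) * spacing
      if (sum((p - center)^2) <= radius^2) cnt <- cnt + 1L
    }
  cnt
}

# Small deterministic survival fixture used across survival-core tests.
survFixture <- function() {
  data.frame(
    pfs_time  = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
    pfs_event = c(1, 0, 1, 1, 0, 1, 1, 0, 1, 1),
    grp       = rep(c("a", "b"), 5),
    x         = c(0, 1, 0, 1, 1, 0, 1, 0, 1, 0))
}

# Cohort with derived convenience columns used by the modelling layer.
makeCohort <- function(n, seed, ...) {
  co <- generateCohort(cohortSpec(n = n, seed = seed, ...))
  co$sex_male <- as.numeric(co$sex == "M")
  co$regimen_rb <- as.numeric(co$regimen == "R-B")
  co
}

# Independent voxel-center ellipsoid test (mirrors the documented rule).
ellipsoidMaskForTest <- function(dims, spacing, center, r) {
  out <- array(FALSE, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      p <- (c(i, j, k) - 0.5) * spacing
      out[i, j, k] <- sum(((p - center) / r)^2) <= 1
    }
  out
}

# In-sample AIC of the adjusted RCS Cox fit, computed without the
# knot-selection machinery (uses the exported pieces only).
coxRcsFitForTest <- function(data, k) {
  kn <- rcsKnots(data$tmtv, k)
  b <- rcsBasis(data$tmtv, kn)
  d <- data
  for (j in seq_len(ncol(b))) d[[paste0("rc", j)]] <- b[, j]
  coxFit(d, paste0("rc", seq_len(ncol(b))))$aic
}
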