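# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct, brute-force implementation kept deliberately
# separate from the package's code paths.

# Exhaustive enumeration of maximal qualifying VT runs: every (i, j)
# window is tested directly against the rule, then non-maximal windows
# are discarded.
brute_vt_runs <- function(beat_ms, paced, thr = 130, min_run = 3L) {
  n <- length(beat_ms)
  qualifies <- function(i, j) {
    if (j - i + 1L < min_run) return(FALSE)
    if (any(paced[i:j])) return(FALSE)
    all(diff(beat_ms[i:j]) < thr)
  }
  wins <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j <= n && qualifies(i, j)) wins[[length(wins) + 1L]] <- c(i, j)
    }
  }
  if (!length(wins)) return(list())
  # keep windows not contained in any other qualifying window
  keep <- vapply(seq_along(wins), function(k) {
    w <- wins[[k]]
    !any(vapply(wins, function(v) {
      (v[1] < w[1] && v[2] >= w[2]) || (v[1] <= w[1] && v[2] > w[2])
    }, logical(1)))
  }, logical(1))
  lapply(wins[keep], function(w) list(start = w[1], end = w[2]))
}

# Brute-force minimum pairwise distance between two point sets.
brute_min_distance <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
                (B[, 3] - A[i, 3])^2)
    best <- min(best, min(d))
  }
  best
}

# Analytic sphere-sphere lens volume fraction (lens volume over sphere
# volume) for equal spheres of radius r at center distance D < 2r.
lens_fraction <- function(r, D) {
  lens <- pi * (4 * r + D) * (2 * r - D)^2 / 12
  lens / (4 / 3 * pi * r^3)
}

# Points filling a solid sphere on a regular grid (spacing g).
sphere_grid_points <- function(center, r, g) {
  s <- seq(-r, r, by = g)
  gpts <- as.matrix(expand.grid(x = s, y = s, z = s))
  gpts <- gpts[rowSums(gpts^2) <= r^2, , drop = FALSE]
  sweep(gpts, 2, center, "+")
}

# Voxel-level oracle: voxels (origin-anchored grid, size v) whose center
# lies inside a ball, via direct enumeration.
ball_voxel_keys <- function(center, r, v) {
  lo <- floor((center - r - v) / v)
  hi <- floor((center + r + v) / v)
  g <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                             k = lo[3]:hi[3]))
  ctr <- (g + 0.5) * v
  inside <- rowSums(sweep(ctr, 2, center)^2) <= r^2
  paste(g[inside, 1], g[inside, 2], g[inside, 3], sep = ",")
}

# Minimum distance from a point to a disk-shaped (cylindrical) cluster
# hull: radius r, half-thickness h, axis z, centered at ctr.
cylinder_distance <- function(p, ctr, r, h) {
  dr <- sqrt((p[1] - ctr[1])^2 + (p[2] - ctr[2])^2)
  dz <- abs(p[3] - ctr[3])
  out_r <- max(dr - r, 0)
  out_z <- max(dz - h, 0)
  if (out_r == 0 && out_z == 0) return(-min(r - dr, h - dz))
  sqrt(out_r^2 + out_z^2)
}

# A compact Gaussian blob of localizations for clustering fixtures.
blob <- function(n, center, sd = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(rnorm(n, center[1], sd), rnorm(n, center[2], sd),
        rnorm(n, center[3], sd))
}

loc_table <- function(P, channel = "A", precision = 10) {
  n <- nrow(P)
  data.frame(x_nm = P[, 1], y_nm = P[, 2], z_nm = P[, 3],
             channel = rep(channel, n), frame = seq_len(n),
             precision_nm = rep(precision, n))
}
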