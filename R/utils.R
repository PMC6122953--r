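# Internal helpers shared across modules: seed substreams, geometry,
# grid/voxel hashing. Units are nm (localization, ultrastructure),
# ms (time), mm (mapping pixels), Ohm (impedance) throughout.

#' Derive a reproducible substream seed from a global seed and a label
#'
#' Each synthetic-data generator draws from its own substream so that adding
#' a generator to a pipeline never perturbs the streams of the others. The
#' substream seed is a deterministic hash of the global seed and a label,
#' kept below 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the substream.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483563
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(label)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# 3x3 rotation about the z axis, angle in degrees (counterclockwise).
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), nrow = 3)
}

# 2x2 counterclockwise rotation, degrees.
rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), nrow = 2)
}

# Pairwise squared distances between rows of two matrices (n x d, m x d).
cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# String keys for integer grid cells (rows of an n x 3 integer matrix).
cell_key <- function(ijk) {
  paste(ijk[, 1L], ijk[, 2L], ijk[, 3L], sep = ",")
}

# Offsets of the 27-cell neighborhood.
neighbor_offsets <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
})

# Validate a named config list against a set of allowed keys; used by the
# pipeline stages so that typos in configs fail loudly.
validate_config <- function(config, allowed, where = "config") {
  if (length(config) == 0L) return(invisible(config))
  if (is.null(names(config)) || any(names(config) == "")) {
    stop(where, ": all entries must be named", call. = FALSE)
  }
  bad <- setdiff(names(config), allowed)
  if (length(bad)) {
    stop(where, ": unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(config)
}

# Linear interpolation helper: first index (fractional) at which `y` crosses
# `level` going downward after index `from`. Returns NA if no crossing.
first_downward_crossing <- function(y, level, from = 1L) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  for (i in seq(from, n - 1L)) {
    if (y[i] >= level && y[i + 1L] < level) {
      if (y[i] == y[i + 1L]) return(i)
      return(i + (y[i] - level) / (y[i] - y[i + 1L]))
    }
  }
  NA_real_
}
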