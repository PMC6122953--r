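# Synthetic digitized membrane-trace pairs emulating transmission-EM
# tracings of apposed membranes near a gap-junction edge. Membrane A is a
# gently curved polyline; membrane B is offset from A along the local
# normal by a separation function d(s), where s is arc length (nm) from the
# gap-junction edge anchor at s = 0.

#' Generate a paired membrane trace with ground truth
#'
#' @param length_nm trace length covered from the anchor, nm.
#' @param d_fun separation function of arc length: a single value, a
#'   vector over sample points, or a `function(s_nm)`; must be > 0.
#' @param step_nm sampling step of the digitized polylines, nm.
#' @param jitter_nm Gaussian jitter SD applied to both polylines
#'   (digitization noise), nm.
#' @param curvature_amp_nm,curvature_wavelength_nm amplitude and wavelength
#'   of a sinusoidal bend of membrane A (0 amplitude = straight).
#' @param heart,condition labels attached to the trace.
#' @param seed integer seed.
#' @return list with `pair` (data.frame: trace columns x_nm, y_nm, role
#'   A/B, point_index, anchor flag) and `truth` (`scene_truth` with the
#'   planted d(s)).
#' @export
gen_membrane_traces <- function(length_nm = 400, d_fun = 20, step_nm = 2,
                                jitter_nm = 0, curvature_amp_nm = 0,
                                curvature_wavelength_nm = 400,
                                heart = "H1", condition = "control",
                                seed = 1L) {
  stopifnot(length_nm > 0, step_nm > 0, jitter_nm >= 0,
            curvature_amp_nm >= 0, curvature_wavelength_nm > 0)
  s <- seq(0, length_nm, by = step_nm)
  d <- if (is.function(d_fun)) d_fun(s) else rep_len(as.numeric(d_fun),
                                                     length(s))
  if (any(d <= 0)) stop("separation function d(s) must be > 0 everywhere")

  # Membrane A: x = s along a sinusoidally bent path.
  ax <- s
  ay <- curvature_amp_nm * sin(2 * pi * s / curvature_wavelength_nm)
  # local tangent and unit normal (analytic for the sine path)
  slope <- curvature_amp_nm * 2 * pi / curvature_wavelength_nm *
    cos(2 * pi * s / curvature_wavelength_nm)
  nrm <- sqrt(1 + slope^2)
  nx <- -slope / nrm
  ny <- 1 / nrm
  bx <- ax + d * nx
  by <- ay + d * ny

  # Reject configurations whose offset curve folds back on itself
  # (self-intersection), which happens when d exceeds the radius of
  # curvature of A.
  if (any(diff(bx) <= 0) || .polyline_self_intersects(bx, by)) {
    stop("requested trace is self-intersecting: ",
         "separation exceeds the radius of curvature")
  }

  with_seed(substream_seed(seed, "tem"), {
    if (jitter_nm > 0) {
      ax <- ax + stats::rnorm(length(ax), 0, jitter_nm)
      ay <- ay + stats::rnorm(length(ay), 0, jitter_nm)
      bx <- bx + stats::rnorm(length(bx), 0, jitter_nm)
      by <- by + stats::rnorm(length(by), 0, jitter_nm)
    }
    pair <- rbind(
      data.frame(trace_id = paste0(heart, "_t1"), role = "A",
                 point_index = seq_along(ax), x_nm = ax, y_nm = ay,
                 anchor = seq_along(ax) == 1L),
      data.frame(trace_id = paste0(heart, "_t1"), role = "B",
                 point_index = seq_along(bx), x_nm = bx, y_nm = by,
                 anchor = FALSE))
    pair$heart <- heart
    pair$condition <- condition
    truth <- structure(list(
      modality = "tem", seed = seed, s_nm = s, d_nm = d,
      jitter_nm = jitter_nm, heart = heart, condition = condition),
      class = "scene_truth")
    list(pair = pair, truth = truth)
  })
}

# crude O(n^2) segment-intersection test for short digitized polylines
.polyline_self_intersects <- function(x, y) {
  n <- length(x) - 1L
  if (n < 3L) return(FALSE)
  seg_int <- function(i, j) {
    p1 <- c(x[i], y[i]); p2 <- c(x[i + 1], y[i + 1])
    p3 <- c(x[j], y[j]); p4 <- c(x[j + 1], y[j + 1])
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (seg_int(i, j)) return(TRUE)
    }
  }
  FALSE
}
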