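# Activation mapping and conduction-velocity analysis of optical-mapping
# movies. Activation time is the time of the maximum first derivative of
# the optical action potential (with sub-frame parabolic refinement of the
# derivative peak); velocity vectors come from the gradient of a fitted
# activation surface; CV_L and CV_T are wedge means of vector speeds within
# +/-15 degrees of the fast axis and its perpendicular, and the anisotropy
# ratio is their quotient.

#' Compute a per-pixel activation map from a movie
#'
#' Each pixel trace is smoothed with a moving average, the discrete first
#' derivative is maximized, and the peak is refined to sub-frame precision
#' by parabolic interpolation of the three derivative samples around it.
#' Pixels whose derivative peak-to-noise ratio (peak over the median
#' absolute deviation of the derivative) falls below `snr_min` are masked
#' invalid; a flat trace has zero peak and is always masked.
#'
#' @param movie array ny x nx x n_frames (>= 3 frames).
#' @param frame_rate frames per second.
#' @param pixel_mm pixel size, mm (carried through to velocity analysis).
#' @param pacing_px pacing-site pixel c(x, y); default: earliest valid
#'   pixel.
#' @param smooth_window moving-average window, frames (odd).
#' @param snr_min minimum derivative peak-to-noise ratio.
#' @return an `activation_map`: `time_ms` (ny x nx, ms from first frame),
#'   `valid`, `pacing_px`, `pixel_mm`, `frame_rate`.
#' @export
compute_activation_map <- function(movie, frame_rate, pixel_mm = 0.1,
                                   pacing_px = NULL, smooth_window = 3,
                                   snr_min = 5) {
  stopifnot(length(dim(movie)) == 3, dim(movie)[3] >= 3, frame_rate > 0,
            smooth_window >= 1)
  ny <- dim(movie)[1]; nx <- dim(movie)[2]; nf <- dim(movie)[3]
  dt <- 1000 / frame_rate
  M <- movie
  dim(M) <- c(ny * nx, nf)
  S <- t(M)
  if (smooth_window > 1) {
    S <- stats::filter(S, rep(1 / smooth_window, smooth_window), sides = 2)
    S <- as.matrix(S)
  }
  D <- diff(S)  # (nf-1) x npix, sample k centered between frames k, k+1
  D[is.na(D)] <- 0

  peak <- apply(D, 2, max)
  kstar <- apply(D, 2, which.max)
  noise <- apply(D, 2, stats::mad)
  snr <- peak / (noise + .Machine$double.eps)
  valid <- is.finite(snr) & snr >= snr_min & peak > 0

  # parabolic sub-frame refinement of the derivative peak
  nk <- nrow(D)
  off <- numeric(ncol(D))
  inner <- kstar > 1L & kstar < nk
  i <- which(inner)
  if (length(i)) {
    dm <- D[cbind(kstar[i] - 1L, i)]
    d0 <- D[cbind(kstar[i], i)]
    dp <- D[cbind(kstar[i] + 1L, i)]
    den <- dm - 2 * d0 + dp
    o <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (dm - dp) / den, 0)
    off[i] <- pmax(-0.5, pmin(0.5, o))
  }
  act <- (kstar - 0.5 + off) * dt
  act[!valid] <- NA_real_
  time_ms <- matrix(act, ny, nx)
  vmask <- matrix(valid, ny, nx)
  if (!any(vmask)) stop("no activations detected")

  if (is.null(pacing_px)) {
    w <- which(time_ms == min(time_ms[vmask], na.rm = TRUE), arr.ind = TRUE)
    pacing_px <- c(w[1, 2], w[1, 1])  # (x, y)
  }
  structure(list(time_ms = time_ms, valid = vmask, pacing_px = pacing_px,
                 pixel_mm = pixel_mm, frame_rate = frame_rate),
            class = "activation_map")
}

#' Fit a global parabolic (quadratic) surface to an activation map
#'
#' Ordinary least squares of T(x, y) = a x^2 + b y^2 + c xy + d x + e y + f
#' to the valid pixels, with x, y in mm (pixel centers) and T in ms.
#'
#' @param map an `activation_map`.
#' @return a `parabolic_surface`: `coefficients` (a, b, c, d, e, f),
#'   `rms_ms`, `pixel_mm`.
#' @export
fit_parabolic_surface <- function(map) {
  stopifnot(inherits(map, "activation_map"))
  idx <- which(map$valid, arr.ind = TRUE)
  if (nrow(idx) < 6) stop("fewer than 6 valid pixels")
  x <- idx[, 2] * map$pixel_mm
  y <- idx[, 1] * map$pixel_mm
  T_ <- map$time_ms[idx]
  X <- cbind(x^2, y^2, x * y, x, y, 1)
  qrX <- qr(X)
  if (qrX$rank < 6) {
    stop("rank-deficient design: valid pixels are collinear or too few ",
         "distinct positions for a quadratic surface")
  }
  beta <- qr.coef(qrX, T_)
  rms <- sqrt(mean((X %*% beta - T_)^2))
  structure(list(coefficients = stats::setNames(
    as.numeric(beta), c("a", "b", "c", "d", "e", "f")),
    rms_ms = rms, pixel_mm = map$pixel_mm),
    class = "parabolic_surface")
}

#' Per-pixel conduction-velocity vectors from an activation map
#'
#' The gradient g of the activation surface (ms/mm) gives the velocity
#' vector v = g / |g|^2 (converted to cm/s). By default the surface is
#' estimated locally: a quadratic is fitted in a `window_px` x `window_px`
#' window around each pixel and its gradient evaluated at the center,
#' which tracks the curved isochrones of point-paced waves; the global
#' parabolic surface (`method = "global"`) is retained for comparison.
#' Pixels with |g| below `grad_floor` and pixels within `exclude_px` of
#' the pacing site (the gradient singularity) are masked.
#'
#' @param map an `activation_map`.
#' @param method "local" (windowed quadratic, default) or "global".
#' @param surface optional precomputed `parabolic_surface` for
#'   `method = "global"`.
#' @param window_px local window size, pixels (odd).
#' @param exclude_px pacing-site exclusion radius, pixels; default 3 for
#'   the global surface and `2 * window_px` for the local fit, where the
#'   wavefront curvature of point-paced waves would otherwise bias the
#'   windowed gradients.
#' @param grad_floor minimum |gradient|, ms/mm.
#' @return a `velocity_field`: `vx`, `vy`, `speed` (cm/s, ny x nx),
#'   `valid`, `pacing_px`, `pixel_mm`.
#' @export
velocity_field <- function(map, method = c("local", "global"),
                           surface = NULL, window_px = 7,
                           exclude_px = NULL, grad_floor = 0.02) {
  stopifnot(inherits(map, "activation_map"))
  method <- match.arg(method)
  ny <- nrow(map$time_ms); nx <- ncol(map$time_ms)
  if (is.null(exclude_px)) {
    exclude_px <- if (method == "local") 2 * window_px else 3
  }

  gx <- matrix(NA_real_, ny, nx)
  gy <- matrix(NA_real_, ny, nx)
  if (method == "global") {
    if (is.null(surface)) surface <- fit_parabolic_surface(map)
    co <- surface$coefficients
    xs <- matrix(seq_len(nx) * map$pixel_mm, ny, nx, byrow = TRUE)
    ys <- matrix(seq_len(ny) * map$pixel_mm, ny, nx)
    gx <- 2 * co["a"] * xs + co["c"] * ys + co["d"]
    gy <- 2 * co["b"] * ys + co["c"] * xs + co["e"]
    gx[!map$valid] <- NA; gy[!map$valid] <- NA
  } else {
    stopifnot(window_px >= 3, window_px %% 2 == 1)
    h <- (window_px - 1L) / 2L
    offs <- expand.grid(dy = -h:h, dx = -h:h)
    xo <- offs$dx * map$pixel_mm
    yo <- offs$dy * map$pixel_mm
    Xw <- cbind(xo^2, yo^2, xo * yo, xo, yo, 1)
    Pinv <- solve(crossprod(Xw), t(Xw))  # 6 x w^2; gradient rows 4 (d), 5 (e)
    # stack the shifted copies of the map: rows = window offsets
    Tpad <- matrix(NA_real_, ny + 2 * h, nx + 2 * h)
    Tm <- map$time_ms
    Tm[!map$valid] <- NA
    Tpad[(h + 1):(h + ny), (h + 1):(h + nx)] <- Tm
    W <- matrix(NA_real_, nrow(offs), ny * nx)
    for (k in seq_len(nrow(offs))) {
      W[k, ] <- as.numeric(
        Tpad[(h + 1 + offs$dy[k]):(h + ny + offs$dy[k]),
             (h + 1 + offs$dx[k]):(h + nx + offs$dx[k])])
    }
    full <- colSums(is.na(W)) == 0L
    G <- matrix(NA_real_, 6, ny * nx)
    if (any(full)) G[, full] <- Pinv %*% W[, full, drop = FALSE]
    gx <- matrix(G[4, ], ny, nx)
    gy <- matrix(G[5, ], ny, nx)
  }

  g2 <- gx^2 + gy^2
  ok <- is.finite(g2) & sqrt(g2) >= grad_floor
  if (!is.null(map$pacing_px) && exclude_px > 0) {
    xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    ys <- matrix(seq_len(ny), ny, nx)
    r2 <- (xs - map$pacing_px[1])^2 + (ys - map$pacing_px[2])^2
    ok <- ok & r2 > exclude_px^2
  }
  # v = g / |g|^2 in mm/ms = 100 cm/s
  vx <- ifelse(ok, 100 * gx / g2, NA_real_)
  vy <- ifelse(ok, 100 * gy / g2, NA_real_)
  structure(list(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2), valid = ok,
                 pacing_px = map$pacing_px, pixel_mm = map$pixel_mm),
            class = "velocity_field")
}

#' Summarize conduction velocities along the fast and slow axes
#'
#' The fast axis is the direction (mod 180 degrees) maximizing the mean
#' speed of velocity vectors whose direction lies within
#' `wedge_half_deg` of it, found by a dense angular scan with parabolic
#' refinement of the peak. CV_L is the wedge mean at the fast axis, CV_T
#' the wedge mean at its perpendicular, AR their ratio.
#'
#' @param field a `velocity_field`.
#' @param wedge_half_deg wedge half-angle, degrees (default 15).
#' @param step_deg angular scan step, degrees.
#' @param min_vectors minimum vectors required in each wedge.
#' @return a `cv_summary`: `cv_l_cm_s`, `cv_t_cm_s`, `ar`, `angle_deg`
#'   (fast axis, \[0, 180)), `wedge_half_deg`, `n_l`, `n_t`.
#' @export
cv_summary <- function(field, wedge_half_deg = 15, step_deg = 1,
                       min_vectors = 10) {
  stopifnot(inherits(field, "velocity_field"), wedge_half_deg > 0)
  ok <- which(field$valid & is.finite(field$speed))
  if (!length(ok)) stop("empty velocity field")
  sp <- field$speed[ok]
  ang <- atan2(field$vy[ok], field$vx[ok]) * 180 / pi  # axial, mod 180
  ang <- ang %% 180

  wedge_mean <- function(theta) {
    d <- abs(ang - theta) %% 180
    d <- pmin(d, 180 - d)
    m <- d <= wedge_half_deg
    c(mean = if (any(m)) mean(sp[m]) else NA_real_, n = sum(m))
  }
  thetas <- seq(0, 180 - step_deg, by = step_deg)
  scan <- vapply(thetas, function(th) wedge_mean(th)[1], numeric(1))
  if (all(is.na(scan))) stop("no vectors fall in any wedge")
  k <- which.max(scan)
  # parabolic refinement on the circular scan curve
  km <- if (k == 1) length(scan) else k - 1
  kp <- if (k == length(scan)) 1 else k + 1
  den <- scan[km] - 2 * scan[k] + scan[kp]
  off <- if (is.finite(den) && abs(den) > .Machine$double.eps)
    max(-0.5, min(0.5, 0.5 * (scan[km] - scan[kp]) / den)) else 0
  theta_fast <- (thetas[k] + off * step_deg) %% 180

  wl <- wedge_mean(theta_fast)
  wt <- wedge_mean((theta_fast + 90) %% 180)
  if (wl["n"] < min_vectors || wt["n"] < min_vectors) {
    stop("fewer than ", min_vectors, " vectors in a wedge (",
         wl["n"], " fast, ", wt["n"], " slow)")
  }
  cv_l <- wl[["mean"]]; cv_t <- wt[["mean"]]
  if (cv_l < cv_t) {  # safeguard: keep the fast-axis convention
    tmp <- cv_l; cv_l <- cv_t; cv_t <- tmp
    theta_fast <- (theta_fast + 90) %% 180
    n_l <- wt[["n"]]; n_t <- wl[["n"]]
  } else {
    n_l <- wl[["n"]]; n_t <- wt[["n"]]
  }
  structure(list(cv_l_cm_s = cv_l, cv_t_cm_s = cv_t, ar = cv_l / cv_t,
                 angle_deg = theta_fast, wedge_half_deg = wedge_half_deg,
                 n_l = n_l, n_t = n_t),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf(
    "CV_L = %.1f cm/s, CV_T = %.1f cm/s, AR = %.2f, fast axis %.1f deg\n",
    x$cv_l_cm_s, x$cv_t_cm_s, x$ar, x$angle_deg))
  invisible(x)
}

#' Action-potential duration of a single-AP trace
#'
#' Duration from the activation time (maximum first derivative, sub-frame
#' refined) to the first crossing of peak - level * amplitude after the
#' peak, with linear interpolation between frames. Amplitude is peak minus
#' the pre-activation baseline (median).
#'
#' @param trace numeric fluorescence/voltage trace containing one AP.
#' @param frame_rate frames per second.
#' @param level repolarization level in (0, 1); 0.8 gives APD80.
#' @param on_degenerate what to do when `level <= 0`: "error" or return
#'   the "full" trace duration.
#' @return duration in ms.
#' @export
apd <- function(trace, frame_rate, level = 0.8,
                on_degenerate = c("error", "full")) {
  stopifnot(length(trace) >= 3, frame_rate > 0)
  on_degenerate <- match.arg(on_degenerate)
  dt <- 1000 / frame_rate
  if (level <= 0) {
    if (on_degenerate == "error") stop("repolarization level must be > 0")
    return((length(trace) - 1) * dt)
  }
  if (level >= 1) stop("repolarization level must be < 1")
  d <- diff(trace)
  k <- which.max(d)
  off <- 0
  if (k > 1 && k < length(d)) {
    den <- d[k - 1] - 2 * d[k] + d[k + 1]
    if (abs(den) > .Machine$double.eps) {
      off <- max(-0.5, min(0.5, 0.5 * (d[k - 1] - d[k + 1]) / den))
    }
  }
  t_act <- (k - 0.5 + off) * dt
  baseline <- if (k > 1) stats::median(trace[seq_len(k)]) else trace[1]
  pk_i <- which.max(trace)
  peak <- trace[pk_i]
  if (peak <= baseline) stop("no action potential found (peak <= baseline)")
  thr <- peak - level * (peak - baseline)
  cross <- first_downward_crossing(trace, thr, from = pk_i)
  if (is.na(cross)) {
    stop("no repolarization crossing of level ", level, " within the trace")
  }
  (cross - 1) * dt - t_act
}

#' Activation delay between two mapped sites
#'
#' @param map an `activation_map`.
#' @param siteA,siteB pixels c(x, y), 1-based.
#' @return T(siteB) - T(siteA), ms.
#' @export
activation_delay <- function(map, siteA, siteB) {
  stopifnot(inherits(map, "activation_map"))
  get <- function(s, nm) {
    if (s[1] < 1 || s[1] > ncol(map$time_ms) ||
        s[2] < 1 || s[2] > nrow(map$time_ms) || !map$valid[s[2], s[1]]) {
      stop("invalid site ", nm, " (outside the map or masked)")
    }
    map$time_ms[s[2], s[1]]
  }
  get(siteB, "B") - get(siteA, "A")
}
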