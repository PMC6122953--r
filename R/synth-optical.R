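# Synthetic optical-mapping movies: a kinematic anisotropic wave (no ionic
# model) paced from a point site. Activation time at pixel p is
#   t(p) = t0 + sqrt((u / CV_L)^2 + (v / CV_T)^2)
# where (u, v) are the pixel offsets from the pacing site rotated into the
# fiber frame (fast axis at `angle_deg` counterclockwise from +x). Each
# pixel's trace is a stereotyped optical action potential: sigmoidal
# upstroke centered at the activation time, plateau, then exponential
# repolarization, plus white Gaussian noise.

#' Stereotyped optical action-potential template
#'
#' @param t_ms time points, ms.
#' @param t_act_ms activation time (upstroke midpoint), ms.
#' @param amplitude peak amplitude (arbitrary fluorescence units).
#' @param upstroke_tau_ms sigmoid time scale of the upstroke, ms.
#' @param plateau_ms plateau duration before repolarization begins, ms.
#' @param rep_tau_ms exponential repolarization time constant, ms.
#' @return fluorescence values at `t_ms`.
#' @export
ap_template <- function(t_ms, t_act_ms, amplitude = 1, upstroke_tau_ms = 1,
                        plateau_ms = 40, rep_tau_ms = 25) {
  up <- stats::plogis((t_ms - t_act_ms) / upstroke_tau_ms)
  rep_ <- exp(-pmax(0, t_ms - t_act_ms - plateau_ms) / rep_tau_ms)
  amplitude * up * rep_
}

#' Generate a synthetic optical-mapping movie with ground truth
#'
#' @param nx,ny grid size in pixels.
#' @param cv_l_cm_s,cv_t_cm_s longitudinal (fast) and transverse (slow)
#'   conduction velocities, cm/s; `cv_l_cm_s >= cv_t_cm_s > 0`.
#' @param angle_deg fast-axis angle, degrees counterclockwise from +x.
#' @param pixel_mm pixel size, mm.
#' @param frame_rate frames per second.
#' @param pacing_px pacing-site pixel, c(x, y), 1-based; default center.
#' @param t0_ms stimulus time (activation time at the pacing site), ms.
#' @param n_frames number of frames; default covers the full repolarization.
#' @param noise_sd Gaussian noise SD as a fraction of amplitude.
#' @param amplitude,upstroke_tau_ms,plateau_ms,rep_tau_ms AP template
#'   parameters (see [ap_template()]).
#' @param seed integer seed.
#' @return list with `movie` (array ny x nx x n_frames), `frame_rate`,
#'   `pixel_mm`, and `truth` (`scene_truth`: per-pixel activation times and
#'   the planted CV_L, CV_T, fast-axis angle, pacing site).
#' @export
gen_optical_movie <- function(nx = 80, ny = 80,
                              cv_l_cm_s = 50, cv_t_cm_s = 20,
                              angle_deg = 30, pixel_mm = 0.1,
                              frame_rate = 1000,
                              pacing_px = NULL, t0_ms = 20,
                              n_frames = NULL, noise_sd = 0.05,
                              amplitude = 1, upstroke_tau_ms = 1,
                              plateau_ms = 40, rep_tau_ms = 25,
                              seed = 1L) {
  stopifnot(cv_l_cm_s > 0, cv_t_cm_s > 0, frame_rate > 0, pixel_mm > 0,
            nx >= 3, ny >= 3, noise_sd >= 0)
  if (cv_l_cm_s < cv_t_cm_s) {
    stop("cv_l_cm_s must be >= cv_t_cm_s (fast-axis convention)")
  }
  if (is.null(pacing_px)) pacing_px <- c(ceiling(nx / 2), ceiling(ny / 2))

  # pixel centers relative to the pacing site, in mm (x right, y down)
  px <- (seq_len(nx) - pacing_px[1]) * pixel_mm
  py <- (seq_len(ny) - pacing_px[2]) * pixel_mm
  X <- matrix(px, ny, nx, byrow = TRUE)
  Y <- matrix(py, ny, nx)
  th <- angle_deg * pi / 180
  U <- X * cos(th) + Y * sin(th)   # along fast axis
  V <- -X * sin(th) + Y * cos(th)  # along slow axis
  # CV in mm/ms: cm/s * 10 mm/cm / 1000 ms/s
  a <- cv_l_cm_s / 100
  b <- cv_t_cm_s / 100
  act <- t0_ms + sqrt((U / a)^2 + (V / b)^2)  # ms

  dt <- 1000 / frame_rate
  if (is.null(n_frames)) {
    n_frames <- ceiling((max(act) + plateau_ms + 6 * rep_tau_ms) / dt) + 1L
  }
  t_ms <- (seq_len(n_frames) - 1L) * dt
  if (min(act) + 2 * upstroke_tau_ms > max(t_ms)) {
    stop("no pixel activates within the movie: increase n_frames")
  }

  with_seed(substream_seed(seed, "optical"), {
    movie <- array(0, dim = c(ny, nx, n_frames))
    for (f in seq_len(n_frames)) {
      movie[, , f] <- ap_template(t_ms[f], act, amplitude, upstroke_tau_ms,
                                  plateau_ms, rep_tau_ms)
    }
    if (noise_sd > 0) {
      movie <- movie + array(stats::rnorm(length(movie), 0,
                                          noise_sd * amplitude),
                             dim = dim(movie))
    }
    truth <- structure(list(
      modality = "optical", seed = seed,
      cv_l_cm_s = cv_l_cm_s, cv_t_cm_s = cv_t_cm_s,
      angle_deg = angle_deg, pacing_px = pacing_px,
      pixel_mm = pixel_mm, frame_rate = frame_rate,
      t0_ms = t0_ms, activation_ms = act,
      template = list(amplitude = amplitude,
                      upstroke_tau_ms = upstroke_tau_ms,
                      plateau_ms = plateau_ms, rep_tau_ms = rep_tau_ms),
      noise_sd = noise_sd), class = "scene_truth")
    list(movie = movie, frame_rate = frame_rate, pixel_mm = pixel_mm,
         truth = truth)
  })
}
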