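# Synthetic electric cell-substrate impedance series. The monolayer is
# modelled with a junctional-resistance term that is flat across the
# low-frequency band the analysis averages (62.5-4000 Hz) by construction:
#   Re Z(f, t) = R_electrode(f) + R_junction(t) * g(f)
# with g(f) = 1 for f <= 4000 Hz and rolling off above the band; Im Z is a
# capacitive term. This reproduces the premise that low-frequency real
# impedance reflects junctional (paracellular) resistance.

#' Generate a synthetic impedance series with ground truth
#'
#' @param r_junction junctional resistance trajectory, Ohm: a single value,
#'   a vector over time points (recycled), or a `function(t_s)`.
#' @param duration_s total duration, s (default 3 h).
#' @param interval_s sampling interval, s (default 90 s; a 3 h run then has
#'   121 time points, 0..10800 s inclusive).
#' @param freqs_hz measurement frequencies, Hz (default 62.5 * 2^(0:10),
#'   i.e. 62.5 to 64000 Hz).
#' @param r_electrode_ohm electrode-series resistance spectrum: single
#'   value, vector over `freqs_hz`, or `function(f)`.
#' @param capacitance_uF effective capacitance for the imaginary part, uF.
#' @param noise_sd_ohm Gaussian noise SD added to Re and Im, Ohm.
#' @param well,condition labels attached to the series.
#' @param seed integer seed.
#' @return list with `series` (long data.frame: time_s, frequency_hz,
#'   re_ohm, im_ohm, well, condition) and `truth` (`scene_truth` with the
#'   true R_junction(t) and the configuration).
#' @export
gen_ecis_series <- function(r_junction = 500,
                            duration_s = 10800, interval_s = 90,
                            freqs_hz = 62.5 * 2^(0:10),
                            r_electrode_ohm = 0,
                            capacitance_uF = 5,
                            noise_sd_ohm = 0,
                            well = "W1", condition = "control",
                            seed = 1L) {
  stopifnot(length(freqs_hz) >= 1, all(freqs_hz > 0), interval_s > 0,
            duration_s >= 0, noise_sd_ohm >= 0)
  freqs_hz <- sort(freqs_hz)
  t_s <- seq(0, duration_s, by = interval_s)
  rj <- if (is.function(r_junction)) r_junction(t_s) else
    rep_len(as.numeric(r_junction), length(t_s))
  re_el <- if (is.function(r_electrode_ohm)) r_electrode_ohm(freqs_hz) else
    rep_len(as.numeric(r_electrode_ohm), length(freqs_hz))
  g <- ifelse(freqs_hz <= 4000, 1, 4000 / freqs_hz)

  with_seed(substream_seed(seed, "ecis"), {
    grid <- expand.grid(fi = seq_along(freqs_hz), ti = seq_along(t_s))
    re <- re_el[grid$fi] + rj[grid$ti] * g[grid$fi]
    im <- -1 / (2 * pi * freqs_hz[grid$fi] * capacitance_uF * 1e-6)
    if (noise_sd_ohm > 0) {
      re <- re + stats::rnorm(length(re), 0, noise_sd_ohm)
      im <- im + stats::rnorm(length(im), 0, noise_sd_ohm)
    }
    series <- data.frame(time_s = t_s[grid$ti],
                         frequency_hz = freqs_hz[grid$fi],
                         re_ohm = re, im_ohm = im,
                         well = well, condition = condition)
    truth <- structure(list(
      modality = "ecis", seed = seed, time_s = t_s,
      r_junction_ohm = rj, freqs_hz = freqs_hz,
      r_electrode_ohm = re_el, band_g = g,
      noise_sd_ohm = noise_sd_ohm), class = "scene_truth")
    list(series = series, truth = truth)
  })
}

#' Logistic monolayer-attachment trajectory
#'
#' Convenience trajectory for attachment-kinetics simulations: resistance
#' rising from `r0` to `r0 + dr` with logistic half-time `t_half_s` and
#' time scale `tau_s`.
#'
#' @param r0 baseline resistance, Ohm.
#' @param dr asymptotic rise, Ohm.
#' @param t_half_s half-rise time, s.
#' @param tau_s logistic time scale, s.
#' @return `function(t_s)` suitable for `r_junction`.
#' @export
logistic_attachment <- function(r0 = 200, dr = 800, t_half_s = 6 * 3600,
                                tau_s = 2 * 3600) {
  function(t_s) r0 + dr * stats::plogis((t_s - t_half_s) / tau_s)
}
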