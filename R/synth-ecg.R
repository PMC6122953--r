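# Synthetic volume-conducted ECGs sampled at 1 kHz: a train of stereotyped
# QRS-T complexes at paced beat times, with an optional inserted run of
# short-cycle non-paced beats emulating ventricular tachycardia. The QRS is
# a raised-cosine wave of configurable width (so its onset/offset are
# sharply defined), and the T wave is a half-sine whose geometric end is
# exactly recovered by the tangent method on the noiseless trace.

#' Generate a synthetic ECG with ground truth
#'
#' Beat times are the R-peak times. A VT run, when requested, is inserted
#' after paced beat `vt$after_beat`: `vt$n_beats` non-paced beats at cycle
#' length `vt$cl_ms`, after which pacing resumes on its original grid.
#'
#' @param cl_ms paced basic cycle length, ms.
#' @param n_beats number of paced beats.
#' @param vt `NULL` or `list(after_beat=, n_beats=, cl_ms=)`.
#' @param fs_hz sampling rate, Hz (default 1000).
#' @param qrs_width_ms full QRS duration, ms.
#' @param qrs_amp_mv R-wave amplitude, mV.
#' @param st_ms isoelectric gap between QRS offset and T-wave onset, ms.
#' @param t_width_ms T-wave duration, ms.
#' @param t_amp_mv T-wave amplitude, mV.
#' @param noise_sd_mv Gaussian noise SD, mV.
#' @param vt_threshold_ms,vt_min_run VT rule used for the planted-run truth
#'   labels (cycle length < threshold, run of at least `vt_min_run`
#'   non-paced beats).
#' @param seed integer seed.
#' @return list with `trace` (data.frame time_ms, mv), `pacing_ms` (paced
#'   stimulus times), and `truth` (`scene_truth`: beat times, paced flags,
#'   per-beat QRS onset/offset and T end, planted VT runs under the rule).
#' @export
gen_ecg <- function(cl_ms = 300, n_beats = 10, vt = NULL, fs_hz = 1000,
                    qrs_width_ms = 30, qrs_amp_mv = 1, st_ms = 40,
                    t_width_ms = 60, t_amp_mv = 0.25, noise_sd_mv = 0,
                    vt_threshold_ms = 130, vt_min_run = 3L, seed = 1L) {
  stopifnot(cl_ms > 0, n_beats >= 1, fs_hz > 0, qrs_width_ms > 0,
            t_width_ms > 0, noise_sd_mv >= 0)
  if (!is.null(vt)) {
    validate_config(vt, c("after_beat", "n_beats", "cl_ms"), "vt")
    stopifnot(vt$cl_ms > 0, vt$n_beats >= 1,
              vt$after_beat >= 1, vt$after_beat <= n_beats)
  }

  complex_span <- qrs_width_ms / 2 + st_ms + t_width_ms  # after the R peak
  lead_in <- qrs_width_ms / 2 + 5

  beats <- (seq_len(n_beats) - 1L) * cl_ms + lead_in + qrs_width_ms / 2
  paced <- rep(TRUE, n_beats)
  if (!is.null(vt)) {
    k <- vt$after_beat
    run <- beats[k] + seq_len(vt$n_beats) * vt$cl_ms
    keep <- beats > run[length(run)] + vt_threshold_ms
    keep[seq_len(k)] <- TRUE
    beats <- c(beats[seq_len(k)], run, beats[keep & seq_along(beats) > k])
    paced <- c(rep(TRUE, k), rep(FALSE, vt$n_beats),
               rep(TRUE, sum(keep & seq_along(paced) > k)))
    o <- order(beats)
    beats <- beats[o]; paced <- paced[o]
  }
  iv <- diff(beats)
  if (any(iv < qrs_width_ms)) {
    stop("overlapping beats: inter-beat interval shorter than the QRS width")
  }

  dur_ms <- max(beats) + complex_span + 20
  t_ms <- seq(0, dur_ms, by = 1000 / fs_hz)
  mv <- numeric(length(t_ms))
  qrs_on <- beats - qrs_width_ms / 2
  qrs_off <- beats + qrs_width_ms / 2
  t_on <- qrs_off + st_ms
  t_end <- t_on + t_width_ms
  for (i in seq_along(beats)) {
    tau <- t_ms - beats[i]
    inq <- abs(tau) < qrs_width_ms / 2
    mv[inq] <- mv[inq] +
      qrs_amp_mv * 0.5 * (1 + cos(2 * pi * tau[inq] / qrs_width_ms))
    tt <- t_ms - t_on[i]
    int_ <- tt > 0 & tt < t_width_ms
    mv[int_] <- mv[int_] + t_amp_mv * sin(pi * tt[int_] / t_width_ms)
  }

  with_seed(substream_seed(seed, "ecg"), {
    if (noise_sd_mv > 0) mv <- mv + stats::rnorm(length(mv), 0, noise_sd_mv)
    runs <- .maximal_vt_runs(beats, paced, vt_threshold_ms, vt_min_run)
    truth <- structure(list(
      modality = "ecg", seed = seed, fs_hz = fs_hz,
      beat_ms = beats, paced = paced,
      qrs_on_ms = qrs_on, qrs_off_ms = qrs_off,
      qrs_width_ms = qrs_width_ms, t_end_ms = t_end,
      qt_ms = t_end - qrs_on, vt_runs = runs,
      vt_threshold_ms = vt_threshold_ms, vt_min_run = vt_min_run),
      class = "scene_truth")
    list(trace = data.frame(time_ms = t_ms, mv = mv),
         pacing_ms = beats[paced] - 8,
         truth = truth)
  })
}

# Maximal runs of consecutive non-paced beats whose every inter-beat
# interval is < threshold; shared by the generator truth and detect_vt().
.maximal_vt_runs <- function(beat_ms, paced, cl_threshold_ms = 130,
                             min_run = 3L) {
  n <- length(beat_ms)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (paced[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && !paced[j + 1L] &&
           (beat_ms[j + 1L] - beat_ms[j]) < cl_threshold_ms) {
      j <- j + 1L
    }
    if (j - i + 1L >= min_run) {
      bt <- beat_ms[i:j]
      out[[length(out) + 1L]] <- list(
        start = i, end = j, n_beats = j - i + 1L, beat_ms = bt,
        mean_cl_ms = mean(diff(bt)), duration_ms = bt[length(bt)] - bt[1])
    }
    i <- j + 1L
  }
  out
}
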