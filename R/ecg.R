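# Beat and ventricular-tachycardia detection in volume-conducted ECGs,
# plus QRS/QT interval measurement. The VT rule is explicit: three or more
# consecutive non-paced beats with every cycle length shorter than 130 ms.

#' Detect beats in an ECG trace
#'
#' Peak detection on the rectified, baseline-corrected signal (running
#' median detrend). Peaks within `pacing_gate_ms` of a pacing event are
#' flagged paced.
#'
#' @param trace data.frame time_ms, mv (uniform sampling).
#' @param pacing_ms optional pacing stimulus times, ms.
#' @param min_prominence peak threshold as a fraction of the largest
#'   rectified deflection.
#' @param refractory_ms minimum spacing between detected beats, ms.
#' @param pacing_gate_ms pacing-flag gate, ms (default +/-10).
#' @return data.frame beat_ms, paced (possibly 0 rows).
#' @export
detect_beats <- function(trace, pacing_ms = NULL, min_prominence = 0.4,
                         refractory_ms = 60, pacing_gate_ms = 10) {
  stopifnot(all(c("time_ms", "mv") %in% names(trace)), nrow(trace) >= 3)
  t <- trace$time_ms
  dt <- stats::median(diff(t))
  x <- trace$mv
  k <- min(length(x) - (1 - length(x) %% 2), 2 * floor(200 / dt / 2) + 1L)
  base <- if (k >= 3) stats::runmed(x, k) else stats::median(x)
  r <- as.numeric(abs(x - base))
  if (max(r) <= 0) {
    return(data.frame(beat_ms = numeric(0), paced = logical(0)))
  }
  pk <- pracma::findpeaks(r, minpeakheight = min_prominence * max(r),
                          minpeakdistance = max(1L, round(refractory_ms / dt)))
  if (is.null(pk)) {
    return(data.frame(beat_ms = numeric(0), paced = logical(0)))
  }
  idx <- sort(pk[, 2])
  beat_ms <- t[idx]
  paced <- rep(FALSE, length(beat_ms))
  if (!is.null(pacing_ms) && length(pacing_ms)) {
    for (i in seq_along(beat_ms)) {
      paced[i] <- any(abs(beat_ms[i] - pacing_ms) <= pacing_gate_ms)
    }
  }
  data.frame(beat_ms = beat_ms, paced = paced)
}

#' Detect ventricular-tachycardia episodes
#'
#' Maximal runs of at least `min_run` consecutive non-paced beats in which
#' every inter-beat interval is shorter than `cl_threshold_ms` (the
#' every-interval reading of the cycle-length rule; `mode = "mean"`
#' instead requires the run's mean cycle length below threshold).
#' Episodes shorter than `min_duration_ms` can optionally be dropped at
#' reporting time; detection itself is duration-free.
#'
#' @param beats data.frame beat_ms, paced (time-ordered), as returned by
#'   [detect_beats()].
#' @param cl_threshold_ms cycle-length threshold, ms (default 130).
#' @param min_run minimum run length in beats (default 3).
#' @param mode "every" (default) or "mean" cycle-length criterion.
#' @param min_duration_ms optional reporting filter, ms.
#' @return list of episodes: start/end beat indices, beat times, number of
#'   beats, mean cycle length, duration.
#' @export
detect_vt <- function(beats, cl_threshold_ms = 130, min_run = 3L,
                      mode = c("every", "mean"), min_duration_ms = NULL) {
  stopifnot(all(c("beat_ms", "paced") %in% names(beats)))
  mode <- match.arg(mode)
  if (is.unsorted(beats$beat_ms)) stop("beats must be time-ordered")
  if (mode == "every") {
    eps <- .maximal_vt_runs(beats$beat_ms, beats$paced, cl_threshold_ms,
                            min_run)
  } else {
    # maximal all-non-paced runs, qualified by mean cycle length
    eps <- .maximal_vt_runs(beats$beat_ms, beats$paced, Inf, min_run)
    eps <- Filter(function(e) e$mean_cl_ms < cl_threshold_ms, eps)
  }
  if (!is.null(min_duration_ms)) {
    eps <- Filter(function(e) e$duration_ms >= min_duration_ms, eps)
  }
  eps
}

#' Measure QRS duration and QT interval around a beat
#'
#' QRS onset/offset: outermost crossings of a derivative threshold
#' (`deriv_frac` of the maximum |dV/dt| in the beat window), scanning
#' outward from the R peak and tolerating sub-`gap_ms` quiet gaps inside
#' the complex. QT: from QRS onset to the T-wave end located by the
#' tangent method (intersection of the steepest T-downslope tangent with
#' the isoelectric baseline).
#'
#' @param trace data.frame time_ms, mv.
#' @param beat_ms the beat's R-peak time, ms.
#' @param deriv_frac derivative threshold fraction (default 0.1).
#' @param qrs_window_ms half-window around the R peak searched for the
#'   QRS complex, ms.
#' @param t_search_ms window after QRS offset searched for the T wave, ms.
#' @param gap_ms sub-threshold gap tolerated inside the QRS, ms.
#' @param smooth_ms moving-average smoothing applied before
#'   differentiation, ms.
#' @return list with qrs_ms, qt_ms, qrs_on_ms, qrs_off_ms, t_end_ms
#'   (qt_ms and t_end_ms are NA with a warning when no T wave is found).
#' @export
measure_intervals <- function(trace, beat_ms, deriv_frac = 0.1,
                              qrs_window_ms = 60, t_search_ms = 250,
                              gap_ms = 5, smooth_ms = 5) {
  stopifnot(all(c("time_ms", "mv") %in% names(trace)))
  t <- trace$time_ms
  dt <- stats::median(diff(t))
  mvs <- trace$mv
  if (smooth_ms > dt) {
    w <- max(3L, round(smooth_ms / dt))
    if (w %% 2L == 0L) w <- w + 1L
    f <- as.numeric(stats::filter(mvs, rep(1 / w, w), sides = 2))
    f[is.na(f)] <- mvs[is.na(f)]
    mvs <- f
  }
  win <- which(t >= beat_ms - qrs_window_ms & t <= beat_ms + qrs_window_ms)
  if (length(win) < 5) stop("beat window outside the trace")
  x <- mvs[win]
  tv <- t[win]
  d <- diff(x) / dt
  dmax <- max(abs(d))
  if (dmax <= 0) stop("no deflection in the beat window (baseline only)")
  thr <- deriv_frac * dmax
  above <- abs(d) >= thr
  if (!any(above)) stop("no deflection in the beat window (baseline only)")
  ri <- min(which.min(abs(tv - beat_ms)), length(d))
  gap <- max(1L, round(gap_ms / dt))

  # merge supra-threshold runs separated by quiet gaps < gap, then take
  # the merged run containing (or nearest to) the R peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_runs <- which(r$values)
  merged <- list()
  cur <- c(starts[on_runs[1]], ends[on_runs[1]])
  for (k in on_runs[-1]) {
    if (starts[k] - cur[2] - 1L < gap) {
      cur[2] <- ends[k]
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- c(starts[k], ends[k])
    }
  }
  merged[[length(merged) + 1L]] <- cur
  mid <- vapply(merged, function(m) (m[1] + m[2]) / 2, numeric(1))
  inside <- vapply(merged, function(m) ri >= m[1] && ri <= m[2], logical(1))
  pick <- if (any(inside)) which(inside)[1] else which.min(abs(mid - ri))
  run <- merged[[pick]]
  # derivative sample k spans (tv[k], tv[k+1]): onset at the left edge of
  # the first supra-threshold sample, offset at the right edge of the last
  qrs_on <- tv[run[1]]
  qrs_off <- tv[min(run[2] + 1L, length(tv))]
  qrs <- qrs_off - qrs_on

  # T wave end by the tangent method, searched after the QRS offset
  baseline <- stats::median(
    mvs[t >= beat_ms - 3 * qrs_window_ms & t < qrs_on])
  ts <- which(t > qrs_off + 2 & t <= qrs_off + t_search_ms)
  qt <- NA_real_; t_end <- NA_real_
  if (length(ts) > 5) {
    xt <- mvs[ts] - baseline
    pk <- which.max(abs(xt))
    sgn <- sign(xt[pk])
    # require a T deflection clearly above the residual noise floor
    if (abs(xt[pk]) > 0.02 * dmax * dt && pk < length(ts) - 2) {
      dts <- diff(mvs[ts]) / dt
      post <- pk:(length(ts) - 1L)
      sl_i <- post[which.max(-sgn * dts[post])]
      slope <- dts[sl_i]
      if (sgn * slope < 0) {
        t_tan <- t[ts[sl_i]] + dt / 2
        v_tan <- (mvs[ts[sl_i]] + mvs[ts[sl_i] + 1L]) / 2
        t_end <- t_tan + (baseline - v_tan) / slope
        qt <- t_end - qrs_on
      }
    }
  }
  if (is.na(qt)) warning("T-wave end not identifiable; QT masked")
  list(qrs_ms = qrs, qt_ms = qt, qrs_on_ms = qrs_on, qrs_off_ms = qrs_off,
       t_end_ms = t_end)
}
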