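# Junctional-resistance analysis of electric cell-substrate impedance
# series. The junctional (paracellular) resistance is quantified as the
# real component of the impedance averaged over the low-frequency band
# (62.5-4000 Hz); downstream summaries are baseline normalization,
# attachment kinetics (change over a fixed window after plating), and
# dose-response tables.

#' Band-averaged junctional-resistance trace
#'
#' At each time point, the mean over in-band frequencies of Re Z(f, t).
#' In-band means `band_hz[1] <= f <= band_hz[2]` inclusive; the mean is
#' unweighted over whatever frequency grid the instrument provides.
#'
#' @param series long-format impedance data.frame with columns time_s,
#'   frequency_hz, re_ohm (im_ohm optional).
#' @param band_hz frequency band, Hz (default c(62.5, 4000)).
#' @return a `resistance_trace` data.frame: time_s, r_ohm, with the band
#'   and frequencies used as attributes.
#' @export
resistance_trace <- function(series, band_hz = c(62.5, 4000)) {
  stopifnot(all(c("time_s", "frequency_hz", "re_ohm") %in% names(series)),
            length(band_hz) == 2, band_hz[1] <= band_hz[2])
  inb <- series$frequency_hz >= band_hz[1] & series$frequency_hz <= band_hz[2]
  if (!any(inb)) {
    stop("no measured frequency falls inside the band [", band_hz[1], ", ",
         band_hz[2], "] Hz")
  }
  s <- series[inb, , drop = FALSE]
  r <- tapply(s$re_ohm, s$time_s, mean)
  out <- data.frame(time_s = as.numeric(names(r)), r_ohm = as.numeric(r))
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "band_hz") <- band_hz
  attr(out, "freqs_used_hz") <- sort(unique(s$frequency_hz))
  class(out) <- c("resistance_trace", "data.frame")
  out
}

#' Normalize a resistance trace to its baseline mean
#'
#' @param trace a `resistance_trace` (or data.frame time_s, r_ohm).
#' @param baseline_window_s c(start, end) of the baseline window, s.
#' @return data.frame time_s, r_rel (fraction of baseline mean), with the
#'   baseline mean (Ohm) as attribute `baseline_ohm`.
#' @export
normalize_to_baseline <- function(trace, baseline_window_s) {
  stopifnot(all(c("time_s", "r_ohm") %in% names(trace)),
            length(baseline_window_s) == 2)
  inw <- trace$time_s >= baseline_window_s[1] &
    trace$time_s <= baseline_window_s[2]
  if (!any(inw)) stop("baseline window contains no samples")
  b <- mean(trace$r_ohm[inw])
  if (b == 0) stop("baseline mean resistance is zero; cannot normalize")
  out <- data.frame(time_s = trace$time_s, r_rel = trace$r_ohm / b)
  attr(out, "baseline_ohm") <- b
  out
}

#' Resistance change over an attachment window
#'
#' R(t1) - R(t0) with nearest-sample lookup, the standard summary of
#' monolayer attachment kinetics (default window 24 h).
#'
#' @param trace a `resistance_trace`.
#' @param t0_s window start, s.
#' @param t1_s window end, s (default t0 + 24 h).
#' @return resistance change, Ohm.
#' @export
attachment_delta <- function(trace, t0_s, t1_s = t0_s + 24 * 3600) {
  stopifnot(all(c("time_s", "r_ohm") %in% names(trace)))
  rng <- range(trace$time_s)
  if (t0_s < rng[1] || t1_s > rng[2]) {
    stop("trace span [", rng[1], ", ", rng[2], "] s does not cover the ",
         "window [", t0_s, ", ", t1_s, "] s")
  }
  at <- function(t) trace$r_ohm[which.min(abs(trace$time_s - t))]
  at(t1_s) - at(t0_s)
}

#' Dose-response table of an endpoint statistic across replicates
#'
#' @param traces_by_dose named list: one list of `resistance_trace`
#'   replicates per dose (names are dose labels, coerced to numeric for
#'   ordering when possible).
#' @param endpoint `function(trace)` returning a scalar endpoint (e.g.
#'   final normalized resistance or [attachment_delta()]).
#' @return data.frame dose, n, mean, se (se is NA for single replicates).
#' @export
dose_response_table <- function(traces_by_dose, endpoint) {
  stopifnot(is.list(traces_by_dose), length(traces_by_dose) >= 2,
            is.function(endpoint))
  doses <- names(traces_by_dose)
  if (is.null(doses)) stop("traces_by_dose must be a named list")
  n_rep <- lengths(traces_by_dose)
  if (length(unique(n_rep)) > 1) {
    warning("unequal replicate counts across doses: ",
            paste(n_rep, collapse = ", "))
  }
  rows <- lapply(seq_along(traces_by_dose), function(i) {
    vals <- vapply(traces_by_dose[[i]], endpoint, numeric(1))
    data.frame(dose = doses[i], n = length(vals), mean = mean(vals),
               se = if (length(vals) > 1)
                 stats::sd(vals) / sqrt(length(vals)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  num <- suppressWarnings(as.numeric(out$dose))
  if (!anyNA(num)) out <- out[order(num), , drop = FALSE]
  rownames(out) <- NULL
  out
}
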