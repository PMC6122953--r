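# Readers and writers for the formats the pipeline exchanges: localization
# CSV (native and ThunderSTORM-style headers, nm or calibrated px units),
# long-format impedance CSV, membrane-trace CSV, ECG CSV, multi-page TIFF
# movies, and JSON truth/summary sidecars. All distances are normalized to
# nm, times to ms (ECG) or s (impedance) on read.

.read_csv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) == 0) stop("empty file: ", path)
  bad <- which(nf != nf[1])
  if (length(bad)) {
    stop("parse error in ", path, " at line ", bad[1] + 0L, ": expected ",
         nf[1], " fields, found ", nf[bad[1]])
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  }
}

#' Read a localization table
#'
#' Accepts the native header (x_nm, y_nm, z_nm, channel, frame,
#' precision_nm), ThunderSTORM-style headers (`x [nm]`, `y [nm]`,
#' `z [nm]`, `frame`, `uncertainty [nm]`), or a pixel-unit dialect
#' (x_px, y_px, z_px) converted with `nm_per_px`.
#'
#' @param path CSV file.
#' @param nm_per_px calibration for the px dialect, nm per pixel.
#' @return data.frame x_nm, y_nm, z_nm, channel, frame, precision_nm.
#' @export
read_localizations <- function(path, nm_per_px = NULL) {
  df <- .read_csv_checked(path)
  nm <- names(df)
  canon <- function(targets) {
    for (tg in targets) if (tg %in% nm) return(tg)
    NULL
  }
  # ThunderSTORM export headers arrive with the bracketed unit mangled
  # by read.csv into dots
  map <- list(
    x_nm = c("x_nm", "x..nm.", "x.nm."),
    y_nm = c("y_nm", "y..nm.", "y.nm."),
    z_nm = c("z_nm", "z..nm.", "z.nm."),
    frame = c("frame"),
    precision_nm = c("precision_nm", "uncertainty..nm.", "uncertainty.nm."),
    channel = c("channel"))
  out <- list()
  px_cols <- c("x_px", "y_px", "z_px")
  if (all(px_cols %in% nm)) {
    if (is.null(nm_per_px)) {
      stop("px-unit localization file requires nm_per_px calibration: ",
           path)
    }
    out$x_nm <- df$x_px * nm_per_px
    out$y_nm <- df$y_px * nm_per_px
    out$z_nm <- df$z_px * nm_per_px
  } else {
    for (k in c("x_nm", "y_nm", "z_nm")) {
      src <- canon(map[[k]])
      if (is.null(src)) stop("missing required column ", k, " in ", path)
      out[[k]] <- df[[src]]
    }
  }
  for (k in c("channel", "frame", "precision_nm")) {
    src <- canon(map[[k]])
    out[[k]] <- if (is.null(src)) {
      switch(k, channel = "A", frame = 1L, precision_nm = 10)
    } else df[[src]]
  }
  as.data.frame(out)
}

#' Write a localization table
#' @param table data.frame with x_nm, y_nm, z_nm (other columns kept).
#' @param path output CSV.
#' @export
write_localizations <- function(table, path) {
  .require_cols(table, c("x_nm", "y_nm", "z_nm"), "localization table")
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read/write long-format impedance series CSV
#' @param path CSV with time_s, frequency_hz, re_ohm, im_ohm (well,
#'   condition optional).
#' @return data.frame.
#' @export
read_impedance <- function(path) {
  df <- .read_csv_checked(path)
  .require_cols(df, c("time_s", "frequency_hz", "re_ohm"), path)
  df
}

#' @rdname read_impedance
#' @param series impedance data.frame.
#' @export
write_impedance <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Read/write membrane trace CSV
#' @param path CSV with trace_id, role, point_index, x_nm, y_nm, anchor.
#' @return data.frame.
#' @export
read_membrane_traces <- function(path) {
  df <- .read_csv_checked(path)
  .require_cols(df, c("role", "point_index", "x_nm", "y_nm"), path)
  df
}

#' @rdname read_membrane_traces
#' @param traces membrane-trace data.frame.
#' @export
write_membrane_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' Read/write an ECG trace CSV
#' @param path CSV with time_ms, mv.
#' @return data.frame.
#' @export
read_ecg <- function(path) {
  df <- .read_csv_checked(path)
  .require_cols(df, c("time_ms", "mv"), path)
  df
}

#' @rdname read_ecg
#' @param trace ECG data.frame.
#' @export
write_ecg <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an optical-mapping movie as multi-page TIFF
#'
#' Frames are stored as 32-bit float pages scaled to \[0, 1\]; the original
#' range is returned (and stored by [run_stage()] in the manifest) so the
#' scaling is invertible. Activation analysis is amplitude-invariant, so
#' the scaling does not affect downstream results.
#'
#' @param movie array ny x nx x n_frames.
#' @param path TIFF file.
#' @return `write_movie_tiff`: the range c(min, max) used for scaling,
#'   invisibly; `read_movie_tiff`: the movie array (in \[0, 1\] units, or
#'   rescaled when `range` is supplied).
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(length(dim(movie)) == 3)
  rng <- range(movie)
  sc <- if (diff(rng) > 0) (movie - rng[1]) / diff(rng) else movie * 0
  pages <- lapply(seq_len(dim(movie)[3]), function(f) sc[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(rng)
}

#' @rdname write_movie_tiff
#' @param range optional original range to undo the \[0, 1\] scaling.
#' @export
read_movie_tiff <- function(path, range = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  movie <- simplify2array(pages)
  if (!is.null(range)) movie <- movie * diff(range) + range[1]
  movie
}

#' Write an R object (truth, summary, manifest) as JSON
#' @param x list-like object.
#' @param path JSON file.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(.jsonable(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_json_file
#' @export
read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# strip classes/attributes jsonlite cannot round-trip
.jsonable <- function(x) {
  if (is.function(x)) return("<function>")
  if (is.data.frame(x)) return(x)
  if (is.matrix(x)) return(unclass(x))
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, .jsonable))
  }
  unclass(x)
}
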