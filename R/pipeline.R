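# Stage-level pipeline orchestration with a reproducibility manifest.
# Every stage validates its configuration against the known keys, executes
# with a seed-derived substream, writes its outputs into `out_dir`, and
# emits a manifest (config echo + md5, seed, package version) sufficient
# to re-run the stage bit-identically.

.stage_names <- c("synth", "storm-rla", "conduction", "ecis",
                  "ultrastructure", "ecg")

#' Run one pipeline stage
#'
#' Stages: `synth` (config `modality` in storm/optical/ecis/tem/ecg plus
#' the generator's arguments), and the analysis stages `storm-rla`,
#' `conduction`, `ecis`, `ultrastructure`, `ecg`, each reading the files a
#' `synth` stage (or an instrument export in the same format) produced.
#' Unknown stages and unknown config keys are rejected. Outputs and a
#' `manifest.json` are written to `out_dir`; re-running with an identical
#' config and seed reproduces every output byte-identically.
#'
#' @param stage stage name.
#' @param config named list of stage parameters (see details in the stage
#'   functions' documentation); analysis stages take input paths in
#'   `config$in_dir` (defaulting to `out_dir`).
#' @param out_dir output directory (created if needed).
#' @param seed integer global seed.
#' @return named list of output file paths (invisibly includes `manifest`).
#' @export
run_stage <- function(stage, config = list(), out_dir, seed = 1L) {
  if (!stage %in% .stage_names) {
    stop("unknown stage '", stage, "'; usage: one of ",
         paste(.stage_names, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(stage,
    "synth" = .stage_synth(config, out_dir, seed),
    "storm-rla" = .stage_storm_rla(config, out_dir),
    "conduction" = .stage_conduction(config, out_dir),
    "ecis" = .stage_ecis(config, out_dir),
    "ultrastructure" = .stage_ultrastructure(config, out_dir),
    "ecg" = .stage_ecg(config, out_dir))

  cfg_path <- file.path(out_dir, paste0("config_", stage, ".json"))
  write_json_file(config, cfg_path)
  manifest <- list(stage = stage, seed = seed,
                   package = "perinexus",
                   version = as.character(utils::packageVersion("perinexus")),
                   config = .jsonable(config),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   outputs = lapply(out, basename))
  mpath <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  write_json_file(manifest, mpath)
  message("stage ", stage, " done; parameters: ",
          jsonlite::toJSON(.jsonable(config), auto_unbox = TRUE))
  invisible(c(out, list(manifest = mpath)))
}

.cfg_get <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

.call_generator <- function(fn, config, drop, seed) {
  allowed <- setdiff(names(formals(fn)), "seed")
  cfg <- config[setdiff(names(config), drop)]
  validate_config(cfg, allowed, "synth config")
  do.call(fn, c(cfg, list(seed = seed)))
}

.stage_synth <- function(config, out_dir, seed) {
  modality <- config$modality
  if (is.null(modality)) stop("synth stage requires config$modality")
  p <- function(f) file.path(out_dir, f)
  if (modality == "storm") {
    sc <- .call_generator(gen_storm_scene, config, "modality", seed)
    write_localizations(sc$channelA, p("channelA.csv"))
    write_localizations(sc$channelB, p("channelB.csv"))
    utils::write.csv(sc$fiducials_A, p("fiducials_a.csv"), row.names = FALSE)
    utils::write.csv(sc$fiducials_B, p("fiducials_b.csv"), row.names = FALSE)
    write_json_file(sc$truth, p("truth.json"))
    list(channel_a = p("channelA.csv"), channel_b = p("channelB.csv"),
         fiducials_a = p("fiducials_a.csv"),
         fiducials_b = p("fiducials_b.csv"), truth = p("truth.json"))
  } else if (modality == "optical") {
    mv <- .call_generator(gen_optical_movie, config, "modality", seed)
    rng <- write_movie_tiff(mv$movie, p("movie.tif"))
    tr <- mv$truth
    tr$tiff_range <- rng
    write_json_file(tr, p("truth.json"))
    list(movie = p("movie.tif"), truth = p("truth.json"))
  } else if (modality == "ecis") {
    se <- .call_generator(gen_ecis_series, config, "modality", seed)
    write_impedance(se$series, p("series.csv"))
    write_json_file(se$truth, p("truth.json"))
    list(series = p("series.csv"), truth = p("truth.json"))
  } else if (modality == "tem") {
    tp <- .call_generator(gen_membrane_traces, config, "modality", seed)
    write_membrane_traces(tp$pair, p("traces.csv"))
    write_json_file(tp$truth, p("truth.json"))
    list(traces = p("traces.csv"), truth = p("truth.json"))
  } else if (modality == "ecg") {
    eg <- .call_generator(gen_ecg, config, "modality", seed)
    write_ecg(eg$trace, p("trace.csv"))
    utils::write.csv(data.frame(pacing_ms = eg$pacing_ms),
                     p("pacing.csv"), row.names = FALSE)
    write_json_file(eg$truth, p("truth.json"))
    list(trace = p("trace.csv"), pacing = p("pacing.csv"),
         truth = p("truth.json"))
  } else {
    stop("unknown synth modality '", modality, "'")
  }
}

.stage_storm_rla <- function(config, out_dir) {
  validate_config(config, c("in_dir", "channel_a", "channel_b",
                            "fiducials_a", "fiducials_b", "radius_nm",
                            "min_points", "min_cluster_size", "voxel_nm",
                            "dilation_nm", "adjacency_nm", "gate_nm"),
                  "storm-rla config")
  ind <- .cfg_get(config, "in_dir", out_dir)
  rd <- function(key, f) .cfg_get(config, key, file.path(ind, f))
  A <- read_localizations(rd("channel_a", "channelA.csv"))
  B <- read_localizations(rd("channel_b", "channelB.csv"))
  fa <- .read_csv_checked(rd("fiducials_a", "fiducials_a.csv"))
  fb <- .read_csv_checked(rd("fiducials_b", "fiducials_b.csv"))
  res <- storm_rla(A, B, fa, fb,
                   radius_nm = .cfg_get(config, "radius_nm", 30),
                   min_points = .cfg_get(config, "min_points", 5),
                   min_cluster_size = .cfg_get(config, "min_cluster_size", 10),
                   voxel_nm = .cfg_get(config, "voxel_nm", 20),
                   dilation_nm = config$dilation_nm,
                   adjacency_nm = .cfg_get(config, "adjacency_nm", 200),
                   gate_nm = .cfg_get(config, "gate_nm", 500))
  p <- function(f) file.path(out_dir, f)
  s <- res$summary
  write_json_file(list(fractions = as.list(s$fractions),
                       adjacency_nm = s$adjacency_nm,
                       n_partner = nrow(s$per_cluster),
                       n_reference = length(res$voxels_a),
                       n_ties = s$n_ties,
                       registration = if (!is.null(res$transform))
                         .jsonable(res$transform)),
                  p("summary.json"))
  utils::write.csv(s$per_cluster, p("per_cluster.csv"), row.names = FALSE)
  utils::write.csv(s$histogram, p("distance_histogram.csv"),
                   row.names = FALSE)
  list(summary = p("summary.json"), per_cluster = p("per_cluster.csv"),
       histogram = p("distance_histogram.csv"))
}

.stage_conduction <- function(config, out_dir) {
  validate_config(config, c("in_dir", "movie", "frame_rate", "pixel_mm",
                            "pacing_px", "smooth_window", "snr_min",
                            "window_px", "wedge_half_deg", "apd_level"),
                  "conduction config")
  ind <- .cfg_get(config, "in_dir", out_dir)
  movie <- read_movie_tiff(.cfg_get(config, "movie",
                                    file.path(ind, "movie.tif")))
  map <- compute_activation_map(
    movie, frame_rate = .cfg_get(config, "frame_rate", 1000),
    pixel_mm = .cfg_get(config, "pixel_mm", 0.1),
    pacing_px = config$pacing_px,
    smooth_window = .cfg_get(config, "smooth_window", 3),
    snr_min = .cfg_get(config, "snr_min", 5))
  vf <- velocity_field(map, window_px = .cfg_get(config, "window_px", 11))
  cvs <- cv_summary(vf, wedge_half_deg = .cfg_get(config, "wedge_half_deg",
                                                  15))
  p <- function(f) file.path(out_dir, f)
  idx <- which(map$valid, arr.ind = TRUE)
  utils::write.csv(data.frame(x_px = idx[, 2], y_px = idx[, 1],
                              t_ms = map$time_ms[idx]),
                   p("activation.csv"), row.names = FALSE)
  write_json_file(unclass(cvs), p("cv_summary.json"))
  list(activation = p("activation.csv"), cv_summary = p("cv_summary.json"))
}

.stage_ecis <- function(config, out_dir) {
  validate_config(config, c("in_dir", "series", "band_hz",
                            "baseline_window_s"), "ecis config")
  ind <- .cfg_get(config, "in_dir", out_dir)
  series <- read_impedance(.cfg_get(config, "series",
                                    file.path(ind, "series.csv")))
  tr <- resistance_trace(series, .cfg_get(config, "band_hz", c(62.5, 4000)))
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(tr, p("resistance.csv"), row.names = FALSE)
  outs <- list(resistance = p("resistance.csv"))
  bw <- config$baseline_window_s
  if (!is.null(bw)) {
    norm <- normalize_to_baseline(tr, bw)
    utils::write.csv(norm, p("resistance_normalized.csv"),
                     row.names = FALSE)
    outs$normalized <- p("resistance_normalized.csv")
  }
  outs
}

.stage_ultrastructure <- function(config, out_dir) {
  validate_config(config, c("in_dir", "traces", "step_nm", "zone_end_nm"),
                  "ultrastructure config")
  ind <- .cfg_get(config, "in_dir", out_dir)
  traces <- read_membrane_traces(.cfg_get(config, "traces",
                                          file.path(ind, "traces.csv")))
  prof <- width_profile(traces, step_nm = .cfg_get(config, "step_nm", 5),
                        zone_end_nm = .cfg_get(config, "zone_end_nm", 150))
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(prof, p("width_profile.csv"), row.names = FALSE)
  list(profile = p("width_profile.csv"))
}

.stage_ecg <- function(config, out_dir) {
  validate_config(config, c("in_dir", "trace", "pacing", "min_prominence",
                            "refractory_ms", "cl_threshold_ms", "min_run"),
                  "ecg config")
  ind <- .cfg_get(config, "in_dir", out_dir)
  trace <- read_ecg(.cfg_get(config, "trace", file.path(ind, "trace.csv")))
  pacing <- NULL
  ppath <- .cfg_get(config, "pacing", file.path(ind, "pacing.csv"))
  if (file.exists(ppath)) pacing <- .read_csv_checked(ppath)$pacing_ms
  beats <- detect_beats(trace, pacing,
                        min_prominence = .cfg_get(config, "min_prominence",
                                                  0.4),
                        refractory_ms = .cfg_get(config, "refractory_ms", 60))
  eps <- detect_vt(beats,
                   cl_threshold_ms = .cfg_get(config, "cl_threshold_ms", 130),
                   min_run = .cfg_get(config, "min_run", 3))
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(beats, p("beats.csv"), row.names = FALSE)
  write_json_file(list(n_episodes = length(eps), episodes = eps),
                  p("episodes.json"))
  list(beats = p("beats.csv"), episodes = p("episodes.json"))
}

#' Run the synthetic-to-analysis pipeline for one modality
#'
#' Chains a `synth` stage and its matching analysis stage in `out_dir`;
#' the convenience entry used by the end-to-end tests.
#'
#' @param modality one of storm, optical, ecis, tem, ecg.
#' @param synth_config,analysis_config stage configs (see [run_stage()]).
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return list of output paths from both stages.
#' @export
run_pipeline <- function(modality, synth_config = list(),
                         analysis_config = list(), out_dir, seed = 1L) {
  stage2 <- switch(modality, storm = "storm-rla", optical = "conduction",
                   ecis = "ecis", tem = "ultrastructure", ecg = "ecg",
                   stop("unknown modality '", modality, "'"))
  s1 <- run_stage("synth", c(list(modality = modality), synth_config),
                  out_dir, seed)
  s2 <- run_stage(stage2, analysis_config, out_dir, seed)
  c(s1, s2)
}
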