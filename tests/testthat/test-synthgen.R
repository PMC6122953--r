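# Synthetic-data generators: determinism, truth consistency, and the
# degenerate analytic anchors the downstream tests rely on.

test_that("all generators are reproducible under config + seed", {
  s1 <- gen_storm_scene(n_ref = 3, field_nm = c(8000, 8000, 2500), seed = 7)
  s2 <- gen_storm_scene(n_ref = 3, field_nm = c(8000, 8000, 2500), seed = 7)
  expect_identical(s1, s2)
  s3 <- gen_storm_scene(n_ref = 3, field_nm = c(8000, 8000, 2500), seed = 8)
  expect_false(identical(s1$channelA, s3$channelA))

  m1 <- gen_optical_movie(nx = 20, ny = 20, n_frames = 150, seed = 5)
  m2 <- gen_optical_movie(nx = 20, ny = 20, n_frames = 150, seed = 5)
  expect_identical(m1, m2)

  e1 <- gen_ecis_series(noise_sd_ohm = 3, seed = 9)
  expect_identical(e1, gen_ecis_series(noise_sd_ohm = 3, seed = 9))

  t1 <- gen_membrane_traces(jitter_nm = 1, seed = 3)
  expect_identical(t1, gen_membrane_traces(jitter_nm = 1, seed = 3))

  g1 <- gen_ecg(noise_sd_mv = 0.05, seed = 2)
  expect_identical(g1, gen_ecg(noise_sd_mv = 0.05, seed = 2))
})

test_that("zero-noise partner points respect the planted hull gap", {
  sc <- gen_storm_scene(n_ref = 4, field_nm = c(10000, 10000, 3000),
                        sigma_xy_nm = 0, sigma_z_nm = 0,
                        background_per_um3 = 0,
                        edge_distances = 100, seed = 11)
  tr <- sc$truth$clusters
  ta <- tr[tr$channel == "A", ]
  tb <- tr[tr$channel == "B", ]
  B <- cbind(sc$channelB$x_nm, sc$channelB$y_nm, sc$channelB$z_nm)
  # every partner point is at least the planted gap from its reference hull
  for (k in seq_len(nrow(tb))) {
    ref <- ta[tb$ref_id[k], ]
    near <- sqrt((B[, 1] - tb$cx[k])^2 + (B[, 2] - tb$cy[k])^2 +
                   (B[, 3] - tb$cz[k])^2) <= max(tb$r1[k], tb$r2[k],
                                                 tb$r3[k]) + 1
    dmin <- min(apply(B[near, , drop = FALSE], 1, cylinder_distance,
                      ctr = c(ref$cx, ref$cy, ref$cz), r = ref$r1,
                      h = ref$r3))
    expect_gte(dmin, tb$planted_edge_nm[k] - 1e-6)
  }
})

test_that("planted class labels follow the 200 nm rule applied to distances", {
  set.seed(42)
  d <- runif(300, -100, 600)
  expect_identical(edge_distance_class(d),
                   ifelse(d < 0, "overlapping",
                          ifelse(d <= 200, "adjacent", "distant")))
  # a full scene's stored labels are recomputable from its stored distances
  sc <- gen_storm_scene(n_ref = 6, field_nm = c(12000, 12000, 3000),
                        seed = 21)
  tb <- sc$truth$clusters[sc$truth$clusters$channel == "B", ]
  expect_identical(tb$class, edge_distance_class(tb$planted_edge_nm,
                                                 sc$truth$adjacency_nm))
  # empirical class fractions match the rule applied to the sampler
  set.seed(1)
  draws <- edge_distance_sampler()(3000)
  fr <- table(edge_distance_class(draws)) / 3000
  expect_equal(unname(fr[["overlapping"]]), 0.30, tolerance = 0.1)
  expect_equal(unname(fr[["adjacent"]]), 0.45, tolerance = 0.1)
})

test_that("storm generator rejects impossible placements", {
  expect_error(gen_storm_scene(field_nm = c(500, 500, 500), n_ref = 1,
                               ref_radius_nm = c(400, 400)),
               "impossible placement")
  expect_error(gen_storm_scene(field_nm = c(6000, 6000, 2000), n_ref = 50),
               "impossible placement")
})

test_that("optical generator: isotropic wave and template anchors", {
  mv <- gen_optical_movie(nx = 21, ny = 21, cv_l_cm_s = 30, cv_t_cm_s = 30,
                          noise_sd = 0, n_frames = 160, seed = 1)
  act <- mv$truth$activation_ms
  pac <- mv$truth$pacing_px
  # circular isochrones: activation = t0 + r / c
  xs <- matrix((seq_len(21) - pac[1]) * 0.1, 21, 21, byrow = TRUE)
  ys <- matrix((seq_len(21) - pac[2]) * 0.1, 21, 21)
  r_mm <- sqrt(xs^2 + ys^2)
  expect_equal(act, mv$truth$t0_ms + r_mm / 0.3, tolerance = 1e-12)
  # per-pixel max-derivative time equals the planted activation time
  # within one frame (noiseless construction)
  map <- compute_activation_map(mv$movie, 1000, 0.1, smooth_window = 1)
  expect_lt(max(abs(map$time_ms - act)), 1)
  # truth bookkeeping stores the exact planted parameters
  mv2 <- gen_optical_movie(cv_l_cm_s = 50, cv_t_cm_s = 20, angle_deg = 30,
                           nx = 10, ny = 10, n_frames = 200, seed = 1)
  expect_identical(mv2$truth$cv_l_cm_s, 50)
  expect_identical(mv2$truth$cv_t_cm_s, 20)
  expect_identical(mv2$truth$angle_deg, 30)
  expect_error(gen_optical_movie(nx = 30, ny = 30, n_frames = 10),
               "no pixel activates")
})

test_that("ecis generator: band construction and sampling grid", {
  # 3 h at 90 s intervals: 0..10800 inclusive = 121 time points
  se <- gen_ecis_series(r_junction = 500, seed = 1)
  expect_identical(length(unique(se$series$time_s)), 121L)
  tr <- resistance_trace(se$series)
  expect_equal(tr$r_ohm, rep(500, 121), tolerance = 1e-12)
  # linearity: doubling R_junction doubles the band average
  se2 <- gen_ecis_series(r_junction = 1000, seed = 1)
  tr2 <- resistance_trace(se2$series)
  expect_equal(tr2$r_ohm, 2 * tr$r_ohm, tolerance = 1e-12)
})

test_that("membrane generator: separation function is honoured", {
  tp <- gen_membrane_traces(d_fun = 20, length_nm = 200, jitter_nm = 0)
  A <- tp$pair[tp$pair$role == "A", ]
  B <- tp$pair[tp$pair$role == "B", ]
  expect_equal(sqrt((B$x_nm - A$x_nm)^2 + (B$y_nm - A$y_nm)^2),
               rep(20, nrow(A)), tolerance = 1e-9)
  tp2 <- gen_membrane_traces(d_fun = function(s) 5 + 0.5 * s,
                             length_nm = 200)
  expect_equal(tp2$truth$d_nm[tp2$truth$s_nm == 100], 55)
  expect_error(gen_membrane_traces(d_fun = function(s) 5 - 0.1 * s,
                                   length_nm = 100), "> 0")
  # offset exceeding the radius of curvature folds back on itself
  expect_error(gen_membrane_traces(d_fun = 120, length_nm = 400,
                                   curvature_amp_nm = 60,
                                   curvature_wavelength_nm = 200),
               "self-intersect")
})

test_that("ecg generator truth follows the VT rule", {
  g0 <- gen_ecg(cl_ms = 300, n_beats = 10, seed = 1)
  expect_identical(length(g0$truth$beat_ms), 10L)
  expect_true(all(g0$truth$paced))
  expect_identical(length(g0$truth$vt_runs), 0L)

  g5 <- gen_ecg(n_beats = 10, vt = list(after_beat = 5, n_beats = 5,
                                        cl_ms = 120), seed = 1)
  expect_identical(length(g5$truth$vt_runs), 1L)
  expect_identical(g5$truth$vt_runs[[1]]$n_beats, 5L)

  g2 <- gen_ecg(n_beats = 10, vt = list(after_beat = 5, n_beats = 2,
                                        cl_ms = 120), seed = 1)
  expect_identical(length(g2$truth$vt_runs), 0L)

  expect_error(gen_ecg(cl_ms = 20, n_beats = 5, qrs_width_ms = 30),
               "overlapping beats")
})
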