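# Activation mapping, surface fitting, velocity extraction and CV/AR
# summaries, anchored on closed-form planar/circular waves and the
# generator's stored truth.

test_that("activation map recovers truth on clean and noisy movies", {
  mv0 <- gen_optical_movie(nx = 40, ny = 40, noise_sd = 0, seed = 1)
  map0 <- compute_activation_map(mv0$movie, 1000, 0.1)
  expect_true(all(map0$valid))
  expect_lt(max(abs(map0$time_ms - mv0$truth$activation_ms)), 1)

  # a flat trace is masked
  mvf <- mv0$movie
  mvf[1, 1, ] <- 0.5
  mapf <- compute_activation_map(mvf, 1000, 0.1)
  expect_false(mapf$valid[1, 1])

  # 5% amplitude noise: at least 95% of pixels within 2 ms of truth
  mvn <- gen_optical_movie(nx = 40, ny = 40, noise_sd = 0.05, seed = 2)
  mapn <- compute_activation_map(mvn$movie, 1000, 0.1)
  err <- abs(mapn$time_ms - mvn$truth$activation_ms)
  expect_gte(mean(err[mapn$valid] < 2), 0.95)

  # an all-flat movie has no activations
  expect_error(compute_activation_map(array(1, c(4, 4, 10)), 1000),
               "no activations")
})

test_that("parabolic surface fit is exact least squares", {
  co <- c(a = 0.8, b = -0.3, c = 0.25, d = 1.5, e = -2, f = 12)
  ny <- 25; nx <- 30; pmm <- 0.1
  xs <- matrix(seq_len(nx) * pmm, ny, nx, byrow = TRUE)
  ys <- matrix(seq_len(ny) * pmm, ny, nx)
  T_ <- co["a"] * xs^2 + co["b"] * ys^2 + co["c"] * xs * ys +
    co["d"] * xs + co["e"] * ys + co["f"]
  map <- structure(list(time_ms = T_, valid = matrix(TRUE, ny, nx),
                        pixel_mm = pmm, frame_rate = 1000,
                        pacing_px = c(1, 1)), class = "activation_map")
  fit <- fit_parabolic_surface(map)
  expect_equal(unname(fit$coefficients), unname(co), tolerance = 1e-9)
  expect_lt(fit$rms_ms, 1e-9)

  # planar wave T = x / c: only the linear x coefficient survives
  c_mm_ms <- 0.4
  mapp <- map
  mapp$time_ms <- xs / c_mm_ms
  fitp <- fit_parabolic_surface(mapp)
  expect_equal(unname(fitp$coefficients[c("a", "b", "c", "e")]),
               rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(fitp$coefficients["d"]), 1 / c_mm_ms,
               tolerance = 1e-9)

  # collinear valid pixels are a named degeneracy
  mapd <- map
  mapd$valid[, ] <- FALSE
  mapd$valid[3, ] <- TRUE
  expect_error(fit_parabolic_surface(mapd), "rank-deficient")
})

test_that("coefficient error shrinks like 1/sqrt(N) under noise", {
  co <- c(a = 0.5, b = 0.2, c = -0.1, d = 2, e = 1, f = 5)
  make_err <- function(n_px, seeds) {
    pmm <- 3 / n_px  # fixed 3 mm field: more pixels, same leverage
    xs <- matrix(seq_len(n_px) * pmm, n_px, n_px, byrow = TRUE)
    ys <- matrix(seq_len(n_px) * pmm, n_px, n_px)
    T0 <- co["a"] * xs^2 + co["b"] * ys^2 + co["c"] * xs * ys +
      co["d"] * xs + co["e"] * ys + co["f"]
    mean(vapply(seeds, function(s) {
      set.seed(s)
      map <- structure(list(time_ms = T0 + rnorm(length(T0), 0, 0.5),
                            valid = matrix(TRUE, n_px, n_px),
                            pixel_mm = pmm, frame_rate = 1000,
                            pacing_px = c(1, 1)), class = "activation_map")
      sqrt(mean((fit_parabolic_surface(map)$coefficients - co)^2))
    }, numeric(1)))
  }
  # same physical field sampled with 4x the pixels: Monte-Carlo mean
  # coefficient error should drop by ~sqrt(4) = 2
  e1 <- make_err(30, 1:25)
  e2 <- make_err(60, 1:25)
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.6)
})

test_that("velocity field reproduces closed-form planar and circular waves", {
  ny <- 40; nx <- 40; pmm <- 0.1; c_mm_ms <- 0.35  # 35 cm/s
  xs <- matrix(seq_len(nx) * pmm, ny, nx, byrow = TRUE)
  mk <- function(T_) structure(list(time_ms = T_,
                                    valid = matrix(TRUE, ny, nx),
                                    pixel_mm = pmm, frame_rate = 1000,
                                    pacing_px = NULL),
                               class = "activation_map")
  vf <- velocity_field(mk(xs / c_mm_ms))
  sp <- vf$speed[vf$valid]
  expect_equal(sp, rep(100 * c_mm_ms, length(sp)), tolerance = 1e-9)
  # direction +x
  expect_true(all(abs(vf$vy[vf$valid]) < 1e-6))
  expect_true(all(vf$vx[vf$valid] > 0))

  # isotropic circular wave: |v| = c outside the pacing mask
  ys <- matrix(seq_len(ny) * pmm, ny, nx)
  r <- sqrt((xs - 2)^2 + (ys - 2)^2)
  mapc <- mk(r / c_mm_ms)
  mapc$pacing_px <- c(20, 20)
  vfc <- velocity_field(mapc)
  spc <- vfc$speed[vfc$valid]
  expect_lt(max(abs(spc - 100 * c_mm_ms)) / (100 * c_mm_ms), 0.02)
})

test_that("cv summary recovers planted anisotropy and axis", {
  mv <- gen_optical_movie(cv_l_cm_s = 50, cv_t_cm_s = 20, angle_deg = 30,
                          noise_sd = 0, seed = 1)
  map <- compute_activation_map(mv$movie, 1000, 0.1,
                                pacing_px = mv$truth$pacing_px)
  cvs <- cv_summary(velocity_field(map))
  expect_equal(cvs$cv_l_cm_s, 50, tolerance = 0.05)
  expect_equal(cvs$cv_t_cm_s, 20, tolerance = 0.05)
  expect_equal(cvs$ar, 2.5, tolerance = 0.05)
  expect_lt(abs(cvs$angle_deg - 30), 2)
  expect_equal(cvs$ar, cvs$cv_l_cm_s / cvs$cv_t_cm_s, tolerance = 1e-9)

  # isotropic control: AR = 1 within 0.05
  iso <- gen_optical_movie(cv_l_cm_s = 30, cv_t_cm_s = 30, noise_sd = 0,
                           seed = 2)
  mi <- compute_activation_map(iso$movie, 1000, 0.1,
                               pacing_px = iso$truth$pacing_px)
  ci <- cv_summary(velocity_field(mi))
  expect_equal(ci$ar, 1, tolerance = 0.05)
})

test_that("cv summary is equivariant under fast-axis rotation", {
  run <- function(ang) {
    mv <- gen_optical_movie(cv_l_cm_s = 45, cv_t_cm_s = 25,
                            angle_deg = ang, noise_sd = 0, seed = 3)
    map <- compute_activation_map(mv$movie, 1000, 0.1,
                                  pacing_px = mv$truth$pacing_px)
    cv_summary(velocity_field(map))
  }
  a <- run(20); b <- run(50)
  expect_lt(abs((b$angle_deg - a$angle_deg) - 30), 2)
  expect_equal(b$ar, a$ar, tolerance = 0.02)

  # exact 90-degree spatial rotation of the movie rotates the axis 90
  mv <- gen_optical_movie(cv_l_cm_s = 45, cv_t_cm_s = 25, angle_deg = 20,
                          noise_sd = 0, seed = 3)
  rot <- array(0, dim(mv$movie)[c(2, 1, 3)])
  for (f in seq_len(dim(mv$movie)[3])) {
    rot[, , f] <- t(mv$movie[, , f])[, dim(mv$movie)[1]:1]
  }
  mr <- compute_activation_map(rot, 1000, 0.1)
  cr <- cv_summary(velocity_field(mr))
  base <- run(20)
  expect_lt(min(abs(((cr$angle_deg - base$angle_deg) %% 180) - c(90))), 3)
  expect_equal(cr$ar, base$ar, tolerance = 0.02)
})

test_that("cv estimates are stable in frame rate and amplitude", {
  run <- function(frame_rate, amplitude) {
    mv <- gen_optical_movie(cv_l_cm_s = 40, cv_t_cm_s = 25, angle_deg = 10,
                            frame_rate = frame_rate, amplitude = amplitude,
                            noise_sd = 0, seed = 4)
    map <- compute_activation_map(mv$movie, frame_rate, 0.1,
                                  pacing_px = mv$truth$pacing_px)
    cv_summary(velocity_field(map))
  }
  a <- run(1000, 1)
  b <- run(2000, 1)
  expect_equal(b$cv_l_cm_s, a$cv_l_cm_s, tolerance = 0.02)
  expect_equal(b$cv_t_cm_s, a$cv_t_cm_s, tolerance = 0.02)
  # uniform amplitude scaling leaves everything unchanged
  d <- run(1000, 7.5)
  expect_equal(d$cv_l_cm_s, a$cv_l_cm_s, tolerance = 1e-9)
  expect_equal(d$ar, a$ar, tolerance = 1e-9)
})

test_that("apd matches analytic crossings of the template", {
  # square pulse of width w: any level gives w within a frame
  tr <- c(rep(0, 20), rep(1, 30), rep(0, 40))
  expect_lt(abs(apd(tr, 1000, level = 0.5) - 30), 1)
  expect_lt(abs(apd(tr, 1000, level = 0.9) - 30), 1)

  # generator template: compare to the numeric root of the template
  # itself (independent oracle via uniroot)
  t_act <- 20; plateau <- 40; tau <- 25; level <- 0.8
  t_ms <- seq(0, 300, by = 1)
  tr2 <- ap_template(t_ms, t_act, 1, 1, plateau, tau)
  peak <- max(tr2)
  thr <- peak - level * (peak - 0)
  t_peak <- t_ms[which.max(tr2)]
  root <- uniroot(function(t) ap_template(t, t_act, 1, 1, plateau, tau) -
                    thr, c(t_peak, 300))$root
  expect_lt(abs(apd(tr2, 1000, level = level) - (root - t_act)), 1.5)

  # degenerate level honours the configured behaviour
  expect_error(apd(tr2, 1000, level = 0), "level")
  expect_equal(apd(tr2, 1000, level = 0, on_degenerate = "full"),
               (length(tr2) - 1))
  # no repolarization inside the trace
  expect_error(apd(tr2[t_ms <= t_act + 5], 1000, level = 0.8),
               "no repolarization")
})

test_that("activation delay reads the map at the requested sites", {
  ny <- 20; nx <- 20; pmm <- 0.1; c_mm_ms <- 0.4
  xs <- matrix(seq_len(nx) * pmm, ny, nx, byrow = TRUE)
  map <- structure(list(time_ms = xs / c_mm_ms,
                        valid = matrix(TRUE, ny, nx), pixel_mm = pmm,
                        frame_rate = 1000, pacing_px = c(1, 10)),
                   class = "activation_map")
  # planar wave: delay = dx / c
  expect_equal(activation_delay(map, c(5, 10), c(15, 10)),
               10 * pmm / c_mm_ms, tolerance = 1e-9)
  expect_identical(activation_delay(map, c(7, 3), c(7, 3)), 0)
  expect_error(activation_delay(map, c(0, 5), c(3, 3)), "invalid site")

  # synthetic elliptical map: delay matches truth within a frame
  mv <- gen_optical_movie(nx = 40, ny = 40, noise_sd = 0, seed = 5)
  m <- compute_activation_map(mv$movie, 1000, 0.1)
  a <- c(10, 20); b <- c(35, 30)
  want <- mv$truth$activation_ms[b[2], b[1]] -
    mv$truth$activation_ms[a[2], a[1]]
  expect_lt(abs(activation_delay(m, a, b) - want), 1)
})
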