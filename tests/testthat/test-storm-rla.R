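# Relative localization analysis: registration, clustering, voxel
# volumes, overlap, signed distances, and classification, each checked
# against analytic geometry or brute-force oracles.

test_that("registration recovers exact rigid misalignments", {
  set.seed(3)
  fa <- data.frame(x_nm = runif(8, 0, 10000), y_nm = runif(8, 0, 10000),
                   z_nm = runif(8, 0, 2000))
  # pure translation: B = A + v; the inverse of the correction equals v
  v <- c(50, -30, 10)
  fb <- data.frame(x_nm = fa$x_nm + v[1], y_nm = fa$y_nm + v[2],
                   z_nm = fa$z_nm + v[3])
  reg <- register_channels(fa, fb, fb)
  expect_equal(reg$transform$residual_rms_nm, 0, tolerance = 1e-9)
  mis <- invert_rigid_transform(reg$transform)
  expect_equal(mis$translation_nm, v, tolerance = 1e-9)
  expect_equal(reg$transform$rotation, diag(3), tolerance = 1e-12)
  # registered points land back on A
  expect_equal(reg$points$x_nm, fa$x_nm, tolerance = 1e-9)

  # identity misregistration gives the identity transform
  reg0 <- register_channels(fa, fa, fa)
  expect_equal(reg0$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(reg0$transform$translation_nm, c(0, 0, 0), tolerance = 1e-9)

  # known rotation about z recovered to numerical precision
  th <- 5 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  A <- cbind(fa$x_nm, fa$y_nm, fa$z_nm)
  Bm <- A %*% t(R)
  fb2 <- data.frame(x_nm = Bm[, 1], y_nm = Bm[, 2], z_nm = Bm[, 3])
  reg2 <- register_channels(fa, fb2, fb2, gate_nm = Inf)
  ang <- atan2(reg2$transform$rotation[2, 1],
               reg2$transform$rotation[1, 1]) * 180 / pi
  expect_equal(ang, -5, tolerance = 1e-6)
  # orthonormality of the estimated rotation
  expect_equal(crossprod(reg2$transform$rotation), diag(3),
               tolerance = 1e-8)
})

test_that("registration fails loudly on degenerate fiducials", {
  fa2 <- data.frame(x_nm = c(0, 100), y_nm = c(0, 0), z_nm = c(0, 0))
  expect_error(register_channels(fa2, fa2, fa2), "fewer than 3")
  lin <- data.frame(x_nm = c(0, 100, 200, 300), y_nm = 0, z_nm = 0)
  expect_error(register_channels(lin, lin, lin), "collinear")
})

test_that("density clustering finds planted clusters and rejects sparse noise", {
  set.seed(10)
  P <- rbind(blob(60, c(1000, 1000, 1000)), blob(60, c(2000, 1000, 1000)))
  cs <- detect_clusters(loc_table(P))
  expect_identical(length(cs$clusters), 2L)
  # memberships match the construction exactly
  got <- sort(vapply(cs$clusters, function(ix) paste(range(ix),
                                                     collapse = "-"),
                     character(1)))
  expect_identical(got, c("1-60", "61-120"))

  # sparse uniform background: no core points
  set.seed(11)
  bg <- cbind(runif(300, 0, 10000), runif(300, 0, 10000),
              runif(300, 0, 3000))
  expect_identical(length(detect_clusters(loc_table(bg))$clusters), 0L)

  # all points identical: one cluster
  same <- matrix(rep(c(500, 500, 500), each = 12), ncol = 3)
  expect_identical(length(detect_clusters(loc_table(same))$clusters), 1L)

  # empty table is an empty result, not an error
  empty <- detect_clusters(loc_table(matrix(numeric(0), ncol = 3)))
  expect_identical(length(empty$clusters), 0L)
})

test_that("voxelized volumes match analytic anchors", {
  # single point, zero dilation: exactly one voxel
  v1 <- voxelize(matrix(c(55, 55, 55), 1), voxel_nm = 20, dilation_nm = 0)
  expect_identical(nrow(v1$ijk), 1L)
  expect_equal(v1$volume_nm3, 20^3)

  # densely sampled solid sphere, voxel 10: volume within 10% of 4/3 pi r^3
  P <- sphere_grid_points(c(500, 500, 500), 100, 2)
  vs <- voxelize(P, voxel_nm = 10, dilation_nm = 3)
  expect_equal(vs$volume_nm3, 4 / 3 * pi * 100^3,
               tolerance = 0.1)

  # halving the voxel changes the volume by at most one surface shell
  vh <- voxelize(P, voxel_nm = 5, dilation_nm = 3)
  shell <- sum(vs$surface) * 10^3
  expect_lte(abs(vh$volume_nm3 - vs$volume_nm3), shell)
})

test_that("overlap fraction matches the analytic sphere-sphere lens", {
  cA <- c(500, 500, 500)
  r <- 100; D <- 150; v <- 10
  cB <- cA + c(D, 0, 0)
  PA <- sphere_grid_points(cA, r, 2)
  PB <- sphere_grid_points(cB, r, 2)
  vA <- voxelize(PA, v, dilation_nm = 3)
  vB <- voxelize(PB, v, dilation_nm = 3)
  expect_equal(overlap_fraction(vA, vA), 1.0)
  far <- voxelize(sweep(PB, 2, c(500, 0, 0), "+"), v, dilation_nm = 3)
  expect_equal(overlap_fraction(far, vA), 0.0)

  got <- overlap_fraction(vB, vA)
  want <- lens_fraction(r, D)  # ~0.0864
  # voxel-level oracle: same occupancy rule applied to the analytic balls
  kA <- ball_voxel_keys(cA, r, v)
  kB <- ball_voxel_keys(cB, r, v)
  oracle <- length(intersect(kA, kB)) / length(kB)
  # the voxelization error is the oracle-to-analytic gap; the measured
  # fraction must sit within that error (plus sampling slack) of analytic
  vox_err <- abs(oracle - want)
  expect_lt(abs(got - want), vox_err + 0.25 * want)
  expect_error(overlap_fraction(voxelize(PA, 20), vA), "common grid")
})

test_that("signed closest distance has the right sign and magnitude", {
  cA <- c(500, 500, 500); r <- 100; v <- 10
  PA <- sphere_grid_points(cA, r, 2)
  vA <- voxelize(PA, v, dilation_nm = 3)
  mk <- function(D) voxelize(sphere_grid_points(cA + c(D, 0, 0), r, 2), v,
                             dilation_nm = 3)
  # disjoint: D - 2r = +50, within one voxel
  expect_lt(abs(signed_closest_distance(mk(250), vA) - 50), v + 1e-9)
  # overlapping: D - 2r = -50, within one voxel
  expect_lt(abs(signed_closest_distance(mk(150), vA) + 50), v + 1e-9)
  # coincident clusters: minus the inradius, within a voxel
  expect_lt(abs(signed_closest_distance(vA, vA) + r), v + 3)
})

test_that("disjoint signed distance matches the brute-force point oracle", {
  set.seed(77)
  # dilation >= voxel half-diagonal guarantees every point marks a voxel,
  # so the occupancy boundary tracks the extreme points to within half a
  # diagonal per cluster (one voxel diagonal overall)
  v <- 10; dil <- 9
  n_ok <- 0
  for (k in 1:100) {
    cA <- runif(3, 400, 600)
    cB <- cA + runif(3, -400, 400)
    A <- blob(sample(30:500, 1), cA, sd = runif(1, 10, 60))
    B <- blob(sample(30:500, 1), cB, sd = runif(1, 10, 60))
    vA <- voxelize(A, v, dil)
    vB <- voxelize(B, v, dil)
    if (any(vA$keys %in% vB$keys)) next  # oracle covers the disjoint case
    got <- signed_closest_distance(vB, vA)
    want <- brute_min_distance(A, B) - 2 * dil
    if (want < v) next  # near-contact: disjointness itself is grid-dependent
    # the occupancy boundary is ambiguous by up to half a voxel diagonal
    # on each cluster surface: one diagonal per surface overall
    expect_lt(abs(got - want), 2 * sqrt(3) * v)
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 30)  # enough disjoint cases actually exercised
})

test_that("classification follows the adjacency threshold", {
  mkball <- function(ctr) voxelize(sphere_grid_points(ctr, 50, 6), 10, 3)
  ref <- mkball(c(500, 500, 500))
  near <- mkball(c(500 + 100 + 100, 500, 500))   # gap +100 nm
  far <- mkball(c(500 + 100 + 400, 500, 500))    # gap +400 nm
  s <- classify_relative_localization(list(near, far), list(ref))
  expect_identical(s$per_cluster$class, c("adjacent", "distant"))
  expect_equal(sum(s$fractions), 1, tolerance = 1e-9)
  expect_lt(max(abs(s$per_cluster$signed_distance_nm - c(100, 400))), 12)

  # empty reference set: all partners distant at infinite distance
  s0 <- classify_relative_localization(list(near, far), list())
  expect_true(all(s0$per_cluster$class == "distant"))
  expect_true(all(is.infinite(s0$per_cluster$signed_distance_nm)))

  # class/sign/overlap consistency
  ovl <- mkball(c(500 + 60, 500, 500))
  s2 <- classify_relative_localization(list(ovl, near, far), list(ref))
  pc <- s2$per_cluster
  expect_identical(pc$class == "overlapping", pc$signed_distance_nm < 0)
  expect_identical(pc$overlap_fraction > 0, pc$signed_distance_nm < 0)
})

test_that("raising the adjacency threshold never shrinks the near fraction", {
  sc <- gen_storm_scene(n_ref = 10, field_nm = c(14000, 14000, 3000),
                        seed = 5)
  res <- storm_rla(sc$channelA, sc$channelB)
  near <- vapply(c(50, 100, 200, 400, 800), function(thr) {
    s <- classify_relative_localization(res$voxels_b, res$voxels_a,
                                        adjacency_nm = thr)
    unname(s$fractions["overlapping"] + s$fractions["adjacent"])
  }, numeric(1))
  expect_true(all(diff(near) >= -1e-12))
})

test_that("summaries are invariant under a common rigid motion", {
  sc <- gen_storm_scene(n_ref = 6, field_nm = c(12000, 12000, 3000),
                        seed = 13)
  res1 <- storm_rla(sc$channelA, sc$channelB, voxel_nm = 10,
                    dilation_nm = 10)
  xf <- structure(list(rotation = perinexus:::rot_z(25),
                       translation_nm = c(300, -150, 80)),
                  class = "rigid_transform")
  res2 <- storm_rla(apply_rigid_transform(sc$channelA, xf),
                    apply_rigid_transform(sc$channelB, xf), voxel_nm = 10,
                    dilation_nm = 10)
  d1 <- sort(res1$summary$per_cluster$signed_distance_nm)
  d2 <- sort(res2$summary$per_cluster$signed_distance_nm)
  expect_identical(length(d1), length(d2))
  # the grid is axis-aligned, so each cluster surface can move by up to
  # half a voxel diagonal under a rotation: one diagonal overall
  expect_lt(max(abs(d1 - d2)), sqrt(3) * 10)
  expect_equal(res1$summary$fractions, res2$summary$fractions)
})

test_that("planted class fractions are recovered on a default scene", {
  sc <- gen_storm_scene(n_ref = 40, field_nm = c(18000, 18000, 3000),
                        misregistration = list(angle_z_deg = 0.5,
                                               translation_nm = c(60, -40, 20)),
                        seed = 19)
  res <- storm_rla(sc$channelA, sc$channelB, sc$fiducials_A, sc$fiducials_B)
  tb <- sc$truth$clusters[sc$truth$clusters$channel == "B", ]
  planted <- table(factor(tb$class, c("overlapping", "adjacent", "distant")))
  planted <- planted / sum(planted)
  expect_lt(max(abs(res$summary$fractions - as.numeric(planted))), 0.03)
})
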