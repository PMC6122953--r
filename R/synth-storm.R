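# Synthetic two-channel 3D single-molecule localization scenes.
#
# The reference channel carries disk-shaped clusters (gap-junction-plaque
# geometry: an oriented disk of 100-400 nm radius and ~40 nm thickness); the
# partner channel carries ellipsoidal clusters planted at controlled
# hull-to-hull (edge-to-edge) distances from their reference disk, so each
# planted cluster has an unambiguous relative-localization class under the
# 200 nm perinexal adjacency rule. Localization error is modelled as
# anisotropic Gaussian noise (default sigma 10 nm lateral, 25 nm axial,
# matching typical 3D localization precision), plus a uniform Poisson
# background of non-specific localizations.

#' Default sampler of planted edge-to-edge distances
#'
#' Draws distances from three well-separated bands (overlapping
#' U\[-120,-30\], adjacent U\[60,140\], distant U\[280,600\] nm) so that no
#' planted cluster sits near the 0 nm or 200 nm class boundaries, where
#' localization noise and hull dilation would make the planted label
#' ambiguous.
#'
#' @param probs class probabilities (overlapping, adjacent, distant).
#' @return a `function(n)` returning `n` planted distances in nm.
#' @export
edge_distance_sampler <- function(probs = c(0.30, 0.45, 0.25)) {
  stopifnot(length(probs) == 3L, all(probs >= 0), sum(probs) > 0)
  probs <- probs / sum(probs)
  function(n) {
    cls <- sample.int(3L, n, replace = TRUE, prob = probs)
    d <- numeric(n)
    d[cls == 1L] <- stats::runif(sum(cls == 1L), -120, -30)
    d[cls == 2L] <- stats::runif(sum(cls == 2L), 60, 140)
    d[cls == 3L] <- stats::runif(sum(cls == 3L), 280, 600)
    d
  }
}

#' Classify a planted edge-to-edge distance under the perinexal rule
#'
#' @param d_nm signed edge-to-edge distance(s), nm (negative = overlap).
#' @param adjacency_nm adjacency threshold, nm (default 200, the perinexal
#'   extent measured from the gap-junction cluster edge).
#' @return character vector in `{"overlapping","adjacent","distant"}`.
#' @export
edge_distance_class <- function(d_nm, adjacency_nm = 200) {
  ifelse(d_nm < 0, "overlapping",
         ifelse(d_nm <= adjacency_nm, "adjacent", "distant"))
}

#' Generate a synthetic two-channel STORM scene with ground truth
#'
#' Reference-channel clusters are uniformly filled disks (axis along z);
#' each gets `partners_per_ref` ellipsoidal partner clusters placed along a
#' random in-plane direction at a planted hull-to-hull distance drawn from
#' `edge_distances`. Fiducial beads are scattered through the field; an
#' optional rigid misregistration (rotation about z through the field
#' center plus a translation) is applied to the partner channel and its
#' fiducials, emulating imperfect two-color alignment.
#'
#' @param field_nm field of view, c(x, y, z) in nm.
#' @param n_ref number of reference clusters.
#' @param partners_per_ref partner clusters planted per reference cluster.
#' @param ref_radius_nm range of reference disk radii, nm.
#' @param ref_thickness_nm reference disk thickness, nm.
#' @param partner_radii_nm range of partner ellipsoid semi-axes, nm.
#' @param mol_per_ref,mol_per_partner molecules sampled per cluster;
#'   `NULL` (default) draws counts from the labeling densities so that
#'   large and small clusters are equally dense, as in real labeling.
#' @param density_ref_um3,density_partner_um3 labeling density inside
#'   reference / partner clusters, molecules per cubic micron; the
#'   defaults put roughly 10 neighbours inside a 30 nm ball after
#'   localization noise, comfortably above the density-clustering core
#'   threshold.
#' @param edge_distances numeric vector (recycled) or `function(n)` of
#'   planted signed edge-to-edge distances, nm.
#' @param background_per_um3 density of uniform background localizations,
#'   per cubic micron, per channel.
#' @param sigma_xy_nm,sigma_z_nm lateral/axial localization noise SD, nm.
#' @param precision_nm nominal localization precision written to tables, nm.
#' @param n_fiducials number of fiducial beads.
#' @param fiducial_sigma_nm localization noise on fiducial positions, nm.
#' @param misregistration `NULL` (identity) or
#'   `list(angle_z_deg=, translation_nm=)` applied to channel B.
#' @param min_ref_sep_nm minimum center-to-center separation of reference
#'   clusters (placed on a jittered grid).
#' @param adjacency_nm adjacency threshold used for planted class labels.
#' @param seed integer seed; identical config + seed is reproducible.
#' @return list with `channelA`, `channelB` (localization tables:
#'   x_nm, y_nm, z_nm, channel, frame, precision_nm), `fiducials_A`,
#'   `fiducials_B`, and `truth` (a `scene_truth` list with the planted
#'   cluster table, the applied misregistration, and the config echo).
#' @export
gen_storm_scene <- function(field_nm = c(10000, 10000, 3000),
                            n_ref = 9,
                            partners_per_ref = 1,
                            ref_radius_nm = c(100, 180),
                            ref_thickness_nm = 40,
                            partner_radii_nm = c(60, 120),
                            mol_per_ref = NULL,
                            mol_per_partner = NULL,
                            density_ref_um3 = 2e5,
                            density_partner_um3 = 1.3e5,
                            edge_distances = edge_distance_sampler(),
                            background_per_um3 = 0.5,
                            sigma_xy_nm = 10,
                            sigma_z_nm = 25,
                            precision_nm = 10,
                            n_fiducials = 12,
                            fiducial_sigma_nm = 0,
                            misregistration = NULL,
                            min_ref_sep_nm = 2600,
                            adjacency_nm = 200,
                            seed = 1L) {
  stopifnot(length(field_nm) == 3L, all(field_nm > 0),
            sigma_xy_nm >= 0, sigma_z_nm >= 0, background_per_um3 >= 0,
            n_ref >= 1, partners_per_ref >= 0, ref_thickness_nm > 0,
            diff(range(ref_radius_nm)) >= 0, all(ref_radius_nm > 0),
            all(partner_radii_nm > 0))
  cfg <- list(field_nm = field_nm, n_ref = n_ref,
              partners_per_ref = partners_per_ref,
              ref_radius_nm = ref_radius_nm,
              ref_thickness_nm = ref_thickness_nm,
              partner_radii_nm = partner_radii_nm,
              mol_per_ref = mol_per_ref, mol_per_partner = mol_per_partner,
              density_ref_um3 = density_ref_um3,
              density_partner_um3 = density_partner_um3,
              background_per_um3 = background_per_um3,
              sigma_xy_nm = sigma_xy_nm, sigma_z_nm = sigma_z_nm,
              precision_nm = precision_nm, n_fiducials = n_fiducials,
              fiducial_sigma_nm = fiducial_sigma_nm,
              misregistration = misregistration,
              min_ref_sep_nm = min_ref_sep_nm, adjacency_nm = adjacency_nm)

  # Worst-case in-plane reach of a planted pair from the reference center;
  # used as a placement margin so whole clusters stay inside the field.
  reach <- max(ref_radius_nm) + 600 + 2 * max(partner_radii_nm)
  margin <- reach + 6 * max(sigma_xy_nm, sigma_z_nm) + 10
  if (2 * max(ref_radius_nm) > min(field_nm[1:2])) {
    stop("impossible placement: reference cluster larger than the field")
  }

  with_seed(substream_seed(seed, "storm"), {
    # Jittered-grid placement of reference centers.
    nx <- max(1L, floor((field_nm[1] - 2 * margin) / min_ref_sep_nm) + 1L)
    ny <- max(1L, floor((field_nm[2] - 2 * margin) / min_ref_sep_nm) + 1L)
    if (nx * ny < n_ref) {
      stop("impossible placement: field of ", field_nm[1], " x ", field_nm[2],
           " nm cannot hold ", n_ref, " reference clusters at ",
           min_ref_sep_nm, " nm separation")
    }
    grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
    pick <- sample.int(nrow(grid), n_ref)
    jit <- min(200, min_ref_sep_nm / 8)
    cx <- margin + (grid$ix[pick] - 0.5) * (field_nm[1] - 2 * margin) / nx +
      stats::runif(n_ref, -jit, jit)
    cy <- margin + (grid$iy[pick] - 0.5) * (field_nm[2] - 2 * margin) / ny +
      stats::runif(n_ref, -jit, jit)
    zmar <- min(field_nm[3] / 4, 500)
    cz <- stats::runif(n_ref, zmar, field_nm[3] - zmar)

    ref_r <- stats::runif(n_ref, ref_radius_nm[1], ref_radius_nm[2])
    n_partner <- n_ref * partners_per_ref
    if (is.function(edge_distances)) {
      d_plant <- if (n_partner > 0) edge_distances(n_partner) else numeric(0)
    } else {
      d_plant <- rep_len(as.numeric(edge_distances), n_partner)
    }

    clusters <- data.frame(
      id = integer(0), channel = character(0), cx = numeric(0),
      cy = numeric(0), cz = numeric(0), shape = character(0),
      r1 = numeric(0), r2 = numeric(0), r3 = numeric(0),
      n_mol = integer(0), ref_id = integer(0),
      planted_edge_nm = numeric(0), class = character(0))

    ptsA <- list(); ptsB <- list()
    for (i in seq_len(n_ref)) {
      # uniform fill of the disk (cylinder, axis z)
      n <- if (!is.null(mol_per_ref)) mol_per_ref else
        max(20L, stats::rpois(1, density_ref_um3 *
                                pi * ref_r[i]^2 * ref_thickness_nm / 1e9))
      rr <- ref_r[i] * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      p <- cbind(cx[i] + rr * cos(th), cy[i] + rr * sin(th),
                 cz[i] + stats::runif(n, -0.5, 0.5) * ref_thickness_nm)
      ptsA[[length(ptsA) + 1L]] <- p
      clusters <- rbind(clusters, data.frame(
        id = i, channel = "A", cx = cx[i], cy = cy[i], cz = cz[i],
        shape = "disk", r1 = ref_r[i], r2 = ref_r[i],
        r3 = ref_thickness_nm / 2, n_mol = n, ref_id = NA_integer_,
        planted_edge_nm = NA_real_, class = NA_character_))
    }

    pid <- 0L
    for (i in seq_len(n_ref)) {
      for (k in seq_len(partners_per_ref)) {
        pid <- pid + 1L
        d <- d_plant[pid]
        a <- stats::runif(1, partner_radii_nm[1], partner_radii_nm[2])
        b <- stats::runif(1, partner_radii_nm[1], partner_radii_nm[2])
        cc <- stats::runif(1, partner_radii_nm[1],
                           min(partner_radii_nm[2], ref_thickness_nm * 2))
        ang <- stats::runif(1, 0, 2 * pi)
        u <- c(cos(ang), sin(ang), 0)
        w <- c(-sin(ang), cos(ang), 0)
        ctr <- c(cx[i], cy[i], cz[i]) + u * (ref_r[i] + d + a)
        # uniform fill of the ellipsoid, semi-axes (a along u, b, cc)
        n <- if (!is.null(mol_per_partner)) mol_per_partner else
          max(20L, stats::rpois(1, density_partner_um3 *
                                  4 / 3 * pi * a * b * cc / 1e9))
        ball <- matrix(stats::rnorm(3 * n), ncol = 3)
        ball <- ball / sqrt(rowSums(ball^2)) * stats::runif(n)^(1 / 3)
        p <- t(ctr + t(ball[, 1] %o% (a * u) + ball[, 2] %o% (b * w) +
                         ball[, 3] %o% c(0, 0, cc)))
        ptsB[[length(ptsB) + 1L]] <- p
        clusters <- rbind(clusters, data.frame(
          id = pid, channel = "B", cx = ctr[1], cy = ctr[2], cz = ctr[3],
          shape = "ellipsoid", r1 = a, r2 = b, r3 = cc,
          n_mol = n, ref_id = i, planted_edge_nm = d,
          class = edge_distance_class(d, adjacency_nm)))
      }
    }

    mkbg <- function() {
      vol_um3 <- prod(field_nm) / 1e9
      nb <- stats::rpois(1, background_per_um3 * vol_um3)
      cbind(stats::runif(nb, 0, field_nm[1]),
            stats::runif(nb, 0, field_nm[2]),
            stats::runif(nb, 0, field_nm[3]))
    }
    A <- do.call(rbind, c(ptsA, list(mkbg())))
    B <- do.call(rbind, c(ptsB, list(mkbg())))
    if (is.null(A)) A <- matrix(numeric(0), ncol = 3)
    if (is.null(B)) B <- matrix(numeric(0), ncol = 3)

    add_noise <- function(p) {
      if (nrow(p) == 0) return(p)
      p + cbind(stats::rnorm(nrow(p), 0, sigma_xy_nm),
                stats::rnorm(nrow(p), 0, sigma_xy_nm),
                stats::rnorm(nrow(p), 0, sigma_z_nm))
    }
    A <- add_noise(A); B <- add_noise(B)

    fid <- cbind(stats::runif(n_fiducials, 200, field_nm[1] - 200),
                 stats::runif(n_fiducials, 200, field_nm[2] - 200),
                 stats::runif(n_fiducials, 200, field_nm[3] - 200))
    fidB <- fid
    if (fiducial_sigma_nm > 0) {
      fidB <- fidB + matrix(stats::rnorm(length(fidB), 0, fiducial_sigma_nm),
                            ncol = 3)
    }

    ctr_field <- field_nm / 2
    R <- diag(3); tr <- c(0, 0, 0)
    if (!is.null(misregistration)) {
      validate_config(misregistration, c("angle_z_deg", "translation_nm"),
                      "misregistration")
      R <- rot_z(misregistration$angle_z_deg %||% 0)
      tr <- misregistration$translation_nm %||% c(0, 0, 0)
      xf <- function(p) t(R %*% (t(p) - ctr_field) + ctr_field + tr)
      if (nrow(B) > 0) B <- xf(B)
      fidB <- xf(fidB)
    }

    mktab <- function(p, channel) {
      n <- nrow(p)
      data.frame(x_nm = p[, 1], y_nm = p[, 2], z_nm = p[, 3],
                 channel = rep(channel, n),
                 frame = if (n) sample.int(20000L, n, replace = TRUE)
                         else integer(0),
                 precision_nm = if (n)
                   pmax(1, stats::rnorm(n, precision_nm, precision_nm / 8))
                 else numeric(0))
    }

    truth <- structure(list(
      modality = "storm", seed = seed, config = cfg,
      field_nm = field_nm, clusters = clusters,
      adjacency_nm = adjacency_nm,
      misregistration = list(rotation = R, translation_nm = tr,
                             center_nm = ctr_field)),
      class = "scene_truth")

    list(channelA = mktab(A, "A"), channelB = mktab(B, "B"),
         fiducials_A = data.frame(x_nm = fid[, 1], y_nm = fid[, 2],
                                  z_nm = fid[, 3]),
         fiducials_B = data.frame(x_nm = fidB[, 1], y_nm = fidB[, 2],
                                  z_nm = fidB[, 3]),
         truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
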