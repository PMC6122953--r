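# Relative localization analysis of two-channel 3D localization data:
# fiducial-based rigid registration, density-based cluster detection,
# voxelized cluster volumes, volume-overlap fractions, signed edge-to-edge
# distances, and classification of each partner cluster as overlapping,
# adjacent (perinexal, within 200 nm of the reference cluster edge) or
# distant.

# ---- registration ---------------------------------------------------------

#' Register channel B onto channel A using fiducial beads
#'
#' Fiducials are paired by mutual nearest neighbour within `gate_nm`; the
#' least-squares rigid transform (rotation + translation, Kabsch/SVD) that
#' maps the B fiducials onto the A fiducials is estimated and applied to
#' all B localizations.
#'
#' @param fiducials_a,fiducials_b data frames with x_nm, y_nm, z_nm.
#' @param points_b localization table (or matrix) to transform.
#' @param gate_nm pairing gate: mutual nearest neighbours farther apart
#'   than this are not used.
#' @return list with `points` (transformed copy of `points_b`) and
#'   `transform` (class `rigid_transform`: `rotation` 3x3 orthonormal,
#'   `translation_nm`, `residual_rms_nm`, `n_pairs`).
#' @export
register_channels <- function(fiducials_a, fiducials_b, points_b,
                              gate_nm = 500) {
  A <- .xyz_matrix(fiducials_a)
  B <- .xyz_matrix(fiducials_b)
  if (nrow(A) == 0 || nrow(B) == 0) {
    stop("fewer than 3 usable fiducial pairs (empty fiducial table)")
  }
  D2 <- cross_dist2(A, B)
  a2b <- apply(D2, 1, which.min)
  b2a <- apply(D2, 2, which.min)
  mutual <- which(b2a[a2b] == seq_len(nrow(A)))
  keep <- mutual[sqrt(D2[cbind(mutual, a2b[mutual])]) <= gate_nm]
  if (length(keep) < 3L) {
    stop("fewer than 3 usable fiducial pairs within the ", gate_nm,
         " nm gate")
  }
  Ap <- A[keep, , drop = FALSE]
  Bp <- B[a2b[keep], , drop = FALSE]

  Ac <- sweep(Ap, 2, colMeans(Ap))
  s <- svd(Ac)$d
  if (s[2] < max(s[1] * 1e-8, 1e-6)) {
    stop("degenerate fiducial geometry: fiducials are collinear, ",
         "rotation is not identifiable")
  }

  Bc <- sweep(Bp, 2, colMeans(Bp))
  H <- crossprod(Bc, Ac)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- colMeans(Ap) - as.numeric(R %*% colMeans(Bp))
  resid <- Ap - (Bp %*% t(R) + matrix(tr, nrow(Ap), 3, byrow = TRUE))
  rms <- sqrt(mean(rowSums(resid^2)))

  transform <- structure(list(rotation = R, translation_nm = tr,
                              residual_rms_nm = rms,
                              n_pairs = length(keep)),
                         class = "rigid_transform")
  list(points = apply_rigid_transform(points_b, transform),
       transform = transform)
}

#' Apply a rigid transform to a localization table or coordinate matrix
#' @param points data frame with x_nm/y_nm/z_nm columns, or n x 3 matrix.
#' @param transform a `rigid_transform`.
#' @return object of the same shape with transformed coordinates.
#' @export
apply_rigid_transform <- function(points, transform) {
  P <- .xyz_matrix(points)
  Q <- P %*% t(transform$rotation) +
    matrix(transform$translation_nm, nrow(P), 3, byrow = TRUE)
  if (is.data.frame(points)) {
    points$x_nm <- Q[, 1]; points$y_nm <- Q[, 2]; points$z_nm <- Q[, 3]
    points
  } else {
    Q
  }
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_rigid_transform <- function(transform) {
  Rt <- t(transform$rotation)
  structure(list(rotation = Rt,
                 translation_nm = as.numeric(-Rt %*%
                                               transform$translation_nm),
                 residual_rms_nm = transform$residual_rms_nm,
                 n_pairs = transform$n_pairs),
            class = "rigid_transform")
}

.xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  stopifnot(all(c("x_nm", "y_nm", "z_nm") %in% names(x)))
  cbind(x$x_nm, x$y_nm, x$z_nm)
}

# ---- cluster detection ----------------------------------------------------

#' Detect clusters of localized molecules (density-based)
#'
#' DBSCAN with a uniform grid index: a point is a core point if it has at
#' least `min_points` neighbours (itself included) within `radius_nm`;
#' clusters are the connected components of core points plus their border
#' points. Clusters with fewer than `min_cluster_size` members are
#' discarded as background; unclustered points are labelled noise (0).
#'
#' Defaults (radius 30 nm, 5 points, minimum size 10) sit near three times
#' the 10 nm localization precision and are exposed for tuning.
#'
#' @param table localization table (x_nm, y_nm, z_nm) or n x 3 matrix.
#' @param radius_nm neighbourhood radius, nm.
#' @param min_points core-point threshold (neighbours within radius,
#'   self included).
#' @param min_cluster_size smallest reported cluster.
#' @return a `cluster_set`: list with `labels` (0 = noise), `clusters`
#'   (list of member index vectors), `coords`, and the parameters.
#' @export
detect_clusters <- function(table, radius_nm = 30, min_points = 5,
                            min_cluster_size = 10) {
  stopifnot(radius_nm > 0, min_points >= 1, min_cluster_size >= 1)
  P <- .xyz_matrix(table)
  n <- nrow(P)
  if (n == 0) {
    return(structure(list(labels = integer(0), clusters = list(),
                          coords = P, radius_nm = radius_nm,
                          min_points = min_points,
                          min_cluster_size = min_cluster_size),
                     class = "cluster_set"))
  }

  labels <- .dbscan_grid(P, radius_nm, min_points)
  cl <- max(labels, 0L)

  # drop undersized clusters, compact ids
  if (cl > 0L) {
    sizes <- tabulate(labels[labels > 0L], nbins = cl)
    keep <- which(sizes >= min_cluster_size)
    remap <- integer(cl)
    remap[keep] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  clusters <- split(seq_len(n), labels)
  clusters <- clusters[names(clusters) != "0"]
  clusters <- clusters[order(as.integer(names(clusters)))]
  names(clusters) <- NULL
  structure(list(labels = labels, clusters = clusters, coords = P,
                 radius_nm = radius_nm, min_points = min_points,
                 min_cluster_size = min_cluster_size),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters,",
      sum(x$labels == 0L), "noise points of", length(x$labels), "\n")
  invisible(x)
}

# ---- voxelization ---------------------------------------------------------

#' Voxelize a set of points (cluster occupancy and volume)
#'
#' The voxel grid is axis-aligned and anchored at the coordinate origin
#' (voxel i spans [i*s, (i+1)*s)), so grids of different clusters built
#' with the same voxel size are directly comparable. A voxel is occupied
#' when its center lies within `dilation_nm` of a member point; with zero
#' dilation (or when no center qualifies) the voxels containing the
#' points are occupied, so occupancy is never empty. Surface voxels are
#' occupied voxels with at least one unoccupied face neighbour.
#'
#' @param points n x 3 matrix or localization table; or a `cluster_set`
#'   with `cluster` giving the cluster index.
#' @param voxel_nm voxel edge length, nm.
#' @param dilation_nm dilation radius, nm; the analysis default is the
#'   median localization precision of the table.
#' @param cluster cluster index when `points` is a `cluster_set`.
#' @return a `voxel_grid`: `ijk` (occupied voxel indices), `keys`,
#'   `surface` (logical), `voxel_nm`, `dilation_nm`, `volume_nm3`,
#'   `centroid_nm`, `bound_nm` (bounding radius around the centroid).
#' @export
voxelize <- function(points, voxel_nm = 20, dilation_nm = 0, cluster = NULL) {
  stopifnot(voxel_nm > 0, dilation_nm >= 0)
  if (inherits(points, "cluster_set")) {
    stopifnot(!is.null(cluster))
    P <- points$coords[points$clusters[[cluster]], , drop = FALSE]
  } else {
    P <- .xyz_matrix(points)
  }
  if (nrow(P) == 0) stop("cannot voxelize an empty point set")

  base <- floor(P / voxel_nm)
  storage.mode(base) <- "integer"
  if (dilation_nm == 0) {
    occ <- unique(base)
  } else {
    reach <- floor(dilation_nm / voxel_nm + 0.5)
    offs <- as.matrix(expand.grid(-reach:reach, -reach:reach, -reach:reach))
    d2 <- dilation_nm^2
    parts <- vector("list", nrow(offs))
    for (k in seq_len(nrow(offs))) {
      cand <- sweep(base, 2, -offs[k, ])
      ctr <- (cand + 0.5) * voxel_nm
      ok <- rowSums((ctr - P)^2) <= d2
      if (any(ok)) parts[[k]] <- cand[ok, , drop = FALSE]
    }
    occ <- do.call(rbind, parts)
    # a dilation smaller than the voxel can leave no qualifying center;
    # fall back to the containing voxels so occupancy is never empty
    occ <- if (is.null(occ)) unique(base) else unique(occ)
  }
  keys <- cell_key(occ)

  face <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  surface <- rep(FALSE, nrow(occ))
  for (k in 1:6) {
    nb <- cell_key(sweep(occ, 2, -face[k, ]))
    surface <- surface | !(nb %in% keys)
  }
  centers <- (occ + 0.5) * voxel_nm
  centroid <- colMeans(centers)
  structure(list(ijk = occ, keys = keys, surface = surface,
                 voxel_nm = voxel_nm, dilation_nm = dilation_nm,
                 n_points = nrow(P),
                 volume_nm3 = nrow(occ) * voxel_nm^3,
                 centroid_nm = centroid,
                 bound_nm = sqrt(max(rowSums(sweep(centers, 2,
                                                   centroid)^2)))),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d voxels (%d surface), voxel %g nm, volume %.3g nm^3\n",
              nrow(x$ijk), sum(x$surface), x$voxel_nm, x$volume_nm3))
  invisible(x)
}

.voxel_centers <- function(vg, surface_only = FALSE) {
  ijk <- if (surface_only) vg$ijk[vg$surface, , drop = FALSE] else vg$ijk
  (ijk + 0.5) * vg$voxel_nm
}

# ---- overlap and signed distance ------------------------------------------

#' Fraction of a partner cluster's volume shared with a reference cluster
#'
#' Both clusters must be voxelized with the same voxel size (grids are
#' origin-anchored, hence commensurable). The denominator is the partner
#' volume; the reference-denominated fraction is available by swapping the
#' arguments.
#'
#' @param partner,reference `voxel_grid` objects.
#' @return overlap fraction in \[0, 1\].
#' @export
overlap_fraction <- function(partner, reference) {
  .check_common_grid(partner, reference)
  if (nrow(partner$ijk) == 0) stop("zero-volume partner cluster")
  sum(partner$keys %in% reference$keys) / nrow(partner$ijk)
}

#' Signed closest edge-to-edge distance between two voxelized clusters
#'
#' Disjoint clusters: the minimum distance between surface-voxel centers
#' (positive). Overlapping clusters: minus the maximum depth at which any
#' partner voxel sits inside the reference occupancy, where depth is the
#' distance to the nearest reference surface voxel center plus half a
#' voxel (a discrete distance transform), so two clusters overlapping over
#' their full extent report minus the reference inradius.
#'
#' @param partner,reference `voxel_grid` objects on a common grid.
#' @return signed distance in nm (negative = overlapping).
#' @export
signed_closest_distance <- function(partner, reference) {
  .check_common_grid(partner, reference)
  inter <- partner$keys %in% reference$keys
  if (!any(inter)) {
    sp <- .voxel_centers(partner, surface_only = TRUE)
    sr <- .voxel_centers(reference, surface_only = TRUE)
    return(sqrt(min(cross_dist2(sp, sr))))
  }
  pin <- (partner$ijk[inter, , drop = FALSE] + 0.5) * partner$voxel_nm
  sr <- .voxel_centers(reference, surface_only = TRUE)
  depth <- sqrt(apply(cross_dist2(pin, sr), 1, min)) + reference$voxel_nm / 2
  -max(depth)
}

.check_common_grid <- function(a, b) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  if (!isTRUE(all.equal(a$voxel_nm, b$voxel_nm))) {
    stop("clusters must be voxelized on a common grid (same voxel size)")
  }
}

# ---- classification -------------------------------------------------------

#' Classify partner clusters relative to reference clusters
#'
#' Each partner cluster is assigned to its nearest reference cluster by
#' signed edge-to-edge distance and classified as overlapping (distance
#' < 0), adjacent (0 <= distance <= `adjacency_nm`, the perinexal zone
#' extending from the reference cluster edge) or distant. Ties between
#' equidistant reference clusters are broken toward the lower reference
#' id and counted in the summary.
#'
#' @param partner_vox list of `voxel_grid` (partner clusters).
#' @param reference_vox list of `voxel_grid` (reference clusters).
#' @param adjacency_nm adjacency threshold, nm (default 200).
#' @param hist_bin_nm bin width of the signed-distance histogram, nm.
#' @return an `rla_summary`: `per_cluster` data.frame (partner, nearest
#'   reference, signed distance, overlap fraction both ways, class),
#'   `fractions` (named, sums to 1), `histogram` (bin edges in nm +
#'   counts), `overlap_degrees` (overlap fractions among overlapping
#'   clusters), `adjacency_nm`, `n_ties`.
#' @export
classify_relative_localization <- function(partner_vox, reference_vox,
                                           adjacency_nm = 200,
                                           hist_bin_nm = 50) {
  stopifnot(adjacency_nm >= 0)
  np <- length(partner_vox)
  nr <- length(reference_vox)
  if (np == 0) stop("no partner clusters to classify")

  dist_nm <- numeric(np)
  near <- integer(np)
  ovl <- numeric(np)
  ovl_ref <- numeric(np)
  n_ties <- 0L

  if (nr == 0) {
    dist_nm[] <- Inf
    near[] <- NA_integer_
  } else {
    rc <- t(vapply(reference_vox, `[[`, numeric(3), "centroid_nm"))
    rb <- vapply(reference_vox, `[[`, numeric(1), "bound_nm")
    for (i in seq_len(np)) {
      pv <- partner_vox[[i]]
      cd <- sqrt(colSums((t(rc) - pv$centroid_nm)^2))
      lb <- cd - rb - pv$bound_nm  # lower bound on edge distance
      ord <- order(lb)
      best <- Inf; best_j <- NA_integer_
      for (j in ord) {
        if (lb[j] > best) break  # cannot improve
        d <- signed_closest_distance(pv, reference_vox[[j]])
        if (abs(d - best) < 1e-9) n_ties <- n_ties + 1L
        if (d < best - 1e-9 || (abs(d - best) < 1e-9 && j < best_j)) {
          best <- d; best_j <- j
        }
      }
      dist_nm[i] <- best
      near[i] <- best_j
      ovl[i] <- overlap_fraction(pv, reference_vox[[best_j]])
      ovl_ref[i] <- overlap_fraction(reference_vox[[best_j]], pv)
    }
  }

  class <- ifelse(dist_nm < 0, "overlapping",
                  ifelse(dist_nm <= adjacency_nm, "adjacent", "distant"))
  per <- data.frame(partner = seq_len(np), nearest_reference = near,
                    signed_distance_nm = dist_nm,
                    overlap_fraction = ovl,
                    overlap_fraction_reference = ovl_ref,
                    class = class)
  fr <- c(overlapping = mean(class == "overlapping"),
          adjacent = mean(class == "adjacent"),
          distant = mean(class == "distant"))

  fin <- dist_nm[is.finite(dist_nm)]
  if (length(fin)) {
    lo <- floor(min(fin) / hist_bin_nm) * hist_bin_nm
    hi <- ceiling(max(fin) / hist_bin_nm) * hist_bin_nm
    if (hi <= lo) hi <- lo + hist_bin_nm
    breaks <- seq(lo, hi, by = hist_bin_nm)
    cnt <- hist(fin, breaks = breaks, plot = FALSE)$counts
    histo <- data.frame(bin_lo_nm = breaks[-length(breaks)],
                        bin_hi_nm = breaks[-1], count = cnt)
  } else {
    histo <- data.frame(bin_lo_nm = numeric(0), bin_hi_nm = numeric(0),
                        count = integer(0))
  }

  structure(list(per_cluster = per, fractions = fr, histogram = histo,
                 overlap_degrees = ovl[class == "overlapping"],
                 adjacency_nm = adjacency_nm, n_ties = n_ties),
            class = "rla_summary")
}

#' @export
print.rla_summary <- function(x, ...) {
  cat("Relative localization of", nrow(x$per_cluster),
      "partner clusters (adjacency", x$adjacency_nm, "nm):\n")
  print(round(100 * x$fractions, 1))
  invisible(x)
}

# ---- end-to-end convenience ----------------------------------------------

#' Run the full relative-localization analysis on two channels
#'
#' Registers channel B onto channel A (when fiducials are supplied),
#' detects clusters in both channels, voxelizes them on a common grid
#' (dilation defaulting to the median localization precision of each
#' table) and classifies every partner (B) cluster relative to the
#' reference (A) clusters.
#'
#' @param channelA,channelB localization tables (reference / partner).
#' @param fiducials_a,fiducials_b optional fiducial tables for
#'   registration.
#' @param radius_nm,min_points,min_cluster_size cluster-detection
#'   parameters, see [detect_clusters()].
#' @param voxel_nm voxel size, nm.
#' @param dilation_nm dilation radius, nm; `NULL` = median precision.
#' @param adjacency_nm adjacency threshold, nm.
#' @param gate_nm fiducial pairing gate, nm.
#' @return list with `summary` (`rla_summary`), `clusters_a`,
#'   `clusters_b` (`cluster_set`s), `voxels_a`, `voxels_b`, `transform`
#'   (or NULL).
#' @export
storm_rla <- function(channelA, channelB, fiducials_a = NULL,
                      fiducials_b = NULL, radius_nm = 30, min_points = 5,
                      min_cluster_size = 10, voxel_nm = 20,
                      dilation_nm = NULL, adjacency_nm = 200,
                      gate_nm = 500) {
  transform <- NULL
  if (!is.null(fiducials_a) && !is.null(fiducials_b)) {
    reg <- register_channels(fiducials_a, fiducials_b, channelB, gate_nm)
    channelB <- reg$points
    transform <- reg$transform
  }
  dil <- function(tab) {
    if (!is.null(dilation_nm)) return(dilation_nm)
    if (is.data.frame(tab) && "precision_nm" %in% names(tab) &&
        nrow(tab) > 0) stats::median(tab$precision_nm) else 10
  }
  ca <- detect_clusters(channelA, radius_nm, min_points, min_cluster_size)
  cb <- detect_clusters(channelB, radius_nm, min_points, min_cluster_size)
  va <- lapply(seq_along(ca$clusters), function(k)
    voxelize(ca, voxel_nm, dil(channelA), cluster = k))
  vb <- lapply(seq_along(cb$clusters), function(k)
    voxelize(cb, voxel_nm, dil(channelB), cluster = k))
  summary <- classify_relative_localization(vb, va, adjacency_nm)
  list(summary = summary, clusters_a = ca, clusters_b = cb,
       voxels_a = va, voxels_b = vb, transform = transform)
}
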