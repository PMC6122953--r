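# Inter-membrane width profiles from paired digitized membrane traces.
# Distances are measured from points sampled along membrane A (at fixed
# arc-length steps from the gap-junction edge anchor) to the nearest point
# of polyline B (point-to-segment), separating the perinexal zone
# (0 < s <= zone_end, default 150 nm from the gap-junction edge) from
# non-junctional sites farther along the membrane.

#' Inter-membrane width profile of a membrane trace pair
#'
#' @param pair data.frame with columns role ("A"/"B"), point_index, x_nm,
#'   y_nm, and an anchor flag on membrane A marking the gap-junction edge
#'   (s = 0); or a list with elements `A`, `B` (n x 2 matrices) and
#'   `anchor_index`.
#' @param step_nm arc-length sampling step along A, nm.
#' @param zone_end_nm perinexal zone extent from the gap-junction edge, nm.
#' @param max_s_nm profile extent; default the full arc length of A.
#' @param normal_projection if TRUE, measure along the local normal of A
#'   instead of to the nearest point of B (option for near-parallel
#'   traces).
#' @return a `width_profile` data.frame: s_nm, d_nm, zone
#'   ("perinexal"/"non_junctional"; s = 0 labelled "edge"), masked
#'   (TRUE where B does not span opposite A and the sample was dropped).
#' @export
width_profile <- function(pair, step_nm = 5, zone_end_nm = 150,
                          max_s_nm = NULL, normal_projection = FALSE) {
  stopifnot(step_nm > 0, zone_end_nm > 0)
  tr <- .as_trace_pair(pair)
  A <- tr$A; B <- tr$B
  if (nrow(A) < 2 || nrow(B) < 2) stop("polylines need at least 2 points")

  seg <- sqrt(rowSums(diff(A)^2))
  s_of <- c(0, cumsum(seg))
  s0 <- s_of[tr$anchor_index]
  s_rel <- s_of - s0
  smax <- if (is.null(max_s_nm)) max(s_rel) else min(max_s_nm, max(s_rel))
  if (smax < zone_end_nm) {
    stop("trace covers only ", round(smax, 1), " nm past the anchor; ",
         "cannot reach zone_end_nm = ", zone_end_nm)
  }
  s <- seq(0, smax, by = step_nm)

  # point on A at arc length s (linear interpolation along the polyline)
  ax <- stats::approx(s_rel, A[, 1], xout = s)$y
  ay <- stats::approx(s_rel, A[, 2], xout = s)$y
  P <- cbind(ax, ay)

  d <- numeric(length(s))
  masked <- logical(length(s))
  if (normal_projection) {
    tx <- stats::approx(s_rel, c(diff(A[, 1]), tail(diff(A[, 1]), 1)) /
                          c(seg, tail(seg, 1)), xout = s)$y
    ty <- stats::approx(s_rel, c(diff(A[, 2]), tail(diff(A[, 2]), 1)) /
                          c(seg, tail(seg, 1)), xout = s)$y
    for (i in seq_along(s)) {
      hit <- .ray_polyline_distance(P[i, ], c(-ty[i], tx[i]), B)
      if (is.na(hit)) { masked[i] <- TRUE; d[i] <- NA } else d[i] <- hit
    }
  } else {
    for (i in seq_along(s)) {
      pr <- .point_polyline_distance(P[i, ], B)
      d[i] <- pr$dist
      masked[i] <- pr$at_end  # nearest point is a B endpoint: B does not
                              # span opposite A here
    }
    if (any(masked)) {
      warning(sum(masked), " sample(s) masked: membrane B does not span ",
              "opposite membrane A")
      d[masked] <- NA_real_
    }
  }
  zone <- ifelse(s == 0, "edge",
                 ifelse(s <= zone_end_nm, "perinexal", "non_junctional"))
  out <- data.frame(s_nm = s, d_nm = d, zone = zone, masked = masked)
  class(out) <- c("width_profile", "data.frame")
  out
}

# distance from point p to polyline B; flags when the projection falls on
# an endpoint of B (i.e. B ends before spanning opposite p)
.point_polyline_distance <- function(p, B) {
  n <- nrow(B)
  a <- B[-n, , drop = FALSE]
  b <- B[-1, , drop = FALSE]
  ab <- b - a
  ap <- matrix(p, n - 1, 2, byrow = TRUE) - a
  len2 <- rowSums(ab^2)
  t_raw <- ifelse(len2 > 0, rowSums(ap * ab) / len2, 0)
  t <- pmax(0, pmin(1, t_raw))
  proj <- a + ab * t
  d2 <- rowSums((matrix(p, n - 1, 2, byrow = TRUE) - proj)^2)
  k <- which.min(d2)
  # masked only when the foot falls strictly beyond an end of B (B truly
  # does not span opposite p); an exactly perpendicular foot at the end
  # vertex is a valid measurement
  at_end <- (k == 1 && t_raw[1] < -1e-9) ||
    (k == n - 1 && t_raw[n - 1] > 1 + 1e-9)
  list(dist = sqrt(d2[k]), at_end = at_end)
}

# first intersection distance of a ray (both directions, nearest) with B
.ray_polyline_distance <- function(p, dir, B) {
  n <- nrow(B)
  best <- NA_real_
  for (i in seq_len(n - 1)) {
    a <- B[i, ]; b <- B[i + 1, ]
    d2 <- b - a
    den <- dir[1] * d2[2] - dir[2] * d2[1]
    if (abs(den) < 1e-12) next
    t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / den
    u <- ((a[1] - p[1]) * dir[2] - (a[2] - p[2]) * dir[1]) / den
    if (u >= 0 && u <= 1) {
      if (is.na(best) || abs(t) < best) best <- abs(t)
    }
  }
  best
}

.as_trace_pair <- function(pair) {
  if (is.list(pair) && !is.data.frame(pair) &&
      all(c("A", "B") %in% names(pair))) {
    return(list(A = as.matrix(pair$A), B = as.matrix(pair$B),
                anchor_index = pair$anchor_index %||% 1L))
  }
  stopifnot(is.data.frame(pair),
            all(c("role", "point_index", "x_nm", "y_nm") %in% names(pair)))
  A <- pair[pair$role == "A", , drop = FALSE]
  B <- pair[pair$role == "B", , drop = FALSE]
  A <- A[order(A$point_index), ]
  B <- B[order(B$point_index), ]
  anchor <- if ("anchor" %in% names(pair) && any(A$anchor)) {
    which(A$anchor)[1]
  } else 1L
  list(A = cbind(A$x_nm, A$y_nm), B = cbind(B$x_nm, B$y_nm),
       anchor_index = anchor)
}

#' Summarize width profiles hierarchically (profiles -> hearts -> condition)
#'
#' Profiles are averaged within the requested zone, then pooled per heart,
#' and the condition mean +/- SE is computed across hearts (n = hearts,
#' the unit the field reports).
#'
#' @param profiles list of `width_profile` objects.
#' @param heart,condition character vectors parallel to `profiles`.
#' @param zone "perinexal" or "non_junctional".
#' @return data.frame condition, n_hearts, mean_nm, se_nm.
#' @export
summarize_widths <- function(profiles, heart, condition,
                             zone = c("perinexal", "non_junctional")) {
  zone <- match.arg(zone)
  stopifnot(length(profiles) >= 1, length(heart) == length(profiles),
            length(condition) == length(profiles))
  per_prof <- vapply(profiles, function(p) {
    v <- p$d_nm[p$zone == zone & !p$masked]
    if (!length(v)) stop("empty ", zone, " zone in a profile")
    mean(v)
  }, numeric(1))
  ph <- tapply(per_prof, list(condition, heart), mean)
  rows <- lapply(rownames(ph), function(cond) {
    hv <- ph[cond, ]
    hv <- hv[!is.na(hv)]
    data.frame(condition = cond, n_hearts = length(hv), mean_nm = mean(hv),
               se_nm = if (length(hv) > 1)
                 stats::sd(hv) / sqrt(length(hv)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
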