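# Procedural epicardial vein tree (coronary-sinus trunk plus tributaries),
# spline fitting and polyline geometry. The tree provides the anatomically
# accessible positions for the left CRT electrode.

polyline_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(rownorm(diff(pts)))
}

#' Fit a smooth polyline through ordered 3D points
#'
#' Natural cubic splines (one per coordinate) over the cumulative chord-length
#' parameter, resampled at a fixed arc-length step. Endpoints are preserved
#' exactly; duplicated consecutive points are removed before fitting.
#'
#' @param points ordered matrix (k x 3) of points (mm), k >= 3 after
#'   de-duplication.
#' @param step resampling arc-length step (mm).
#' @return Matrix of resampled polyline vertices (mm).
#' @export
fit_vein_spline <- function(points, step = 2) {
  points <- matrix(points, ncol = 3)
  if (nrow(points) >= 2) {
    keep <- c(TRUE, rownorm(diff(points)) > 1e-9)
    points <- points[keep, , drop = FALSE]
  }
  if (nrow(points) < 3) stop("need at least 3 distinct points to fit a vein spline")
  s <- c(0, cumsum(rownorm(diff(points))))
  fx <- stats::splinefun(s, points[, 1], method = "natural")
  fy <- stats::splinefun(s, points[, 2], method = "natural")
  fz <- stats::splinefun(s, points[, 3], method = "natural")
  # dense evaluation, then re-parameterize by true arc length of the curve
  sd <- seq(0, max(s), length.out = max(50L, 10L * nrow(points)))
  dense <- cbind(fx(sd), fy(sd), fz(sd))
  arc <- c(0, cumsum(rownorm(diff(dense))))
  n_out <- max(2L, ceiling(max(arc) / step) + 1L)
  targets <- seq(0, max(arc), length.out = n_out)
  out <- cbind(stats::approx(arc, dense[, 1], xout = targets)$y,
               stats::approx(arc, dense[, 2], xout = targets)$y,
               stats::approx(arc, dense[, 3], xout = targets)$y)
  out[1, ] <- points[1, ]
  out[nrow(out), ] <- points[nrow(points), ]
  out
}

#' Per-point minimum distance between polylines
#'
#' For each vertex of `a`, the minimum Euclidean distance to the segments of
#' `b` (perpendicular foot where the projection falls inside a segment,
#' endpoint distance otherwise).
#'
#' @param a,b polylines (matrices k x 3, mm).
#' @return List with `dist` (per-vertex minima, mm) and `max`.
#' @export
polyline_distance <- function(a, b) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  if (nrow(a) < 1 || nrow(b) < 1) stop("polylines must be non-empty")
  if (nrow(b) == 1) {
    d <- rownorm(a - matrix(b, nrow(a), 3, byrow = TRUE))
    return(list(dist = d, max = max(d)))
  }
  P <- b[-nrow(b), , drop = FALSE]
  Q <- b[-1, , drop = FALSE]
  V <- Q - P
  vv <- pmax(rowdot(V, V), .Machine$double.eps)
  d <- vapply(seq_len(nrow(a)), function(i) {
    W <- matrix(a[i, ], nrow(P), 3, byrow = TRUE) - P
    tpar <- pmin(pmax(rowdot(W, V) / vv, 0), 1)
    foot <- P + tpar * V
    min(rownorm(matrix(a[i, ], nrow(P), 3, byrow = TRUE) - foot))
  }, numeric(1))
  list(dist = d, max = max(d))
}

#' Generate a procedural epicardial vein tree
#'
#' A coronary-sinus trunk running circumferentially near the base of the
#' epicardium plus tributaries descending the lateral/posterolateral/
#' anterolateral wall, built as splines through points sampled on the analytic
#' epicardial surface. Accessible electrode positions are sampled every
#' `step` mm of arc length along every branch.
#'
#' @param mesh an `lv_mesh`.
#' @param seed integer seed (tributary azimuths and waviness draw from it).
#' @param n_tributaries number of descending tributaries (2-4).
#' @param step accessible-position spacing (mm of arc length).
#' @return An object of class `vein_tree`: `branches` (list of polylines),
#'   `branch_names`, and `accessible` (data.frame with branch id, arc length
#'   and x/y/z).
#' @export
generate_vein_tree <- function(mesh, seed = 1L, n_tributaries = 3L, step = 2) {
  stopifnot(n_tributaries >= 2, n_tributaries <= 4)
  rng <- local({ set.seed(seed); list(az = stats::runif(4, -0.25, 0.25),
                                      wob = stats::runif(4, 0.01, 0.04)) })
  branches <- list()
  nm <- character(0)

  # trunk: coronary sinus near the base, sweeping the posterior/lateral wall
  th_tr <- seq(0.45 * pi, 1.8 * pi, length.out = 14)
  ab_tr <- 0.93 + rng$wob[1] * sin(3 * th_tr)
  trunk_pts <- shell_point(mesh, 1, pmin(ab_tr, 0.99), th_tr)
  branches[[1]] <- fit_vein_spline(trunk_pts, step = step)
  nm[1] <- "cs_trunk"

  # tributaries: descend from the trunk towards the apex at lateral-ish azimuths
  base_az <- seq(0.75 * pi, 1.45 * pi, length.out = n_tributaries)
  for (k in seq_len(n_tributaries)) {
    az <- base_az[k] + rng$az[k]
    ab <- seq(0.92, 0.18, length.out = 10)
    th_b <- az + rng$wob[k + 1] * 6 * (0.92 - ab) * sin(seq(0, pi, length.out = 10))
    pts <- shell_point(mesh, 1, ab, th_b)
    branches[[k + 1]] <- fit_vein_spline(pts, step = step)
    nm[k + 1] <- paste0("vein_", k)
  }

  acc <- do.call(rbind, lapply(seq_along(branches), function(bi) {
    pl <- branches[[bi]]
    arc <- c(0, cumsum(rownorm(diff(pl))))
    data.frame(branch = bi, arc = arc, x = pl[, 1], y = pl[, 2], z = pl[, 3])
  }))
  structure(list(branches = branches, branch_names = nm, accessible = acc,
                 step = step, seed = as.integer(seed)),
            class = "vein_tree")
}

#' @export
print.vein_tree <- function(x, ...) {
  cat(sprintf("Epicardial vein tree: %d branches (%s), %d accessible positions\n",
              length(x$branches), paste(x$branch_names, collapse = ", "),
              nrow(x$accessible)))
  invisible(x)
}

# Maximum distance of all vein vertices from the epicardial surface (mm).
vein_surface_distance <- function(mesh, veins) {
  pts <- do.call(rbind, veins$branches)
  proj <- project_to_surface(mesh, pts, tags = "epicardium")
  max(rownorm(pts - proj))
}
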