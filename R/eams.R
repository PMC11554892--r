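# Simulated electro-anatomical mapping clouds and the three-step alignment of
# a mapped cloud to the LV geometry (reference pairs, rigid registration,
# nearest-surface projection).

#' Construct an EAMS cloud object
#' @param points matrix (k x 3) of positions (mm).
#' @param at activation times (s), finite and >= 0.
#' @param region character region tag per point: "septum", "cs" or "lateral".
#' @return An object of class `eams_cloud`.
#' @export
eams_cloud <- function(points, at, region) {
  points <- matrix(points, ncol = 3)
  region <- as.character(region)
  stopifnot(nrow(points) == length(at), length(at) == length(region))
  if (any(!is.finite(at)) || any(at < 0)) stop("activation times must be finite and >= 0")
  bad <- setdiff(unique(region), c("septum", "cs", "lateral"))
  if (length(bad)) stop("unknown EAMS region tag: ", paste(bad, collapse = ", "))
  structure(list(points = points, at = as.numeric(at), region = region),
            class = "eams_cloud")
}

#' @export
print.eams_cloud <- function(x, ...) {
  tab <- table(x$region)
  cat(sprintf("EAMS cloud: %d points (%s); AT range [%.3f, %.3f] s\n",
              nrow(x$points),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              min(x$at), max(x$at)))
  invisible(x)
}

#' Synthesize an EAMS cloud from a truth activation map
#'
#' Emulates the catheter acquisitions used for calibration/validation: points
#' sampled on the septal endocardial patch, along the coronary-sinus trunk of
#' the vein tree, and on the lateral epicardium. The activation time of each
#' point is the interpolated truth time plus additive Gaussian noise truncated
#' at three standard deviations; positions are exact.
#'
#' @param psi activation map (`activation_map`) defined on `mesh` nodes.
#' @param mesh an `lv_mesh`.
#' @param veins a `vein_tree` (coronary-sinus samples are drawn from its trunk
#'   and tributaries).
#' @param counts named vector: points per region, defaults
#'   `c(septum = 10, cs = 40, lateral = 30)` emulating clinical acquisition
#'   counts.
#' @param noise_sd Gaussian time-noise standard deviation (s).
#' @param seed integer seed.
#' @return An `eams_cloud`.
#' @export
synthesize_eams <- function(psi, mesh, veins,
                            counts = c(septum = 10, cs = 40, lateral = 30),
                            noise_sd = 0.005, seed = 1L) {
  stopifnot(inherits(psi, "activation_map"))
  set.seed(seed)
  cts <- c(septum = 10, cs = 40, lateral = 30)
  cts[names(counts)] <- counts

  th <- mesh$theta
  thc <- atan2(sin(th), cos(th))      # (-pi, pi], 0 = mid-septum

  pick_nodes <- function(cand, n, what) {
    if (length(cand) < n) stop(sprintf("requested %d %s points but only %d candidate sites", n, what, length(cand)))
    sample(cand, n)
  }

  pts <- NULL; atv <- NULL; reg <- NULL
  if (cts["septum"] > 0) {
    cand <- which(mesh$phi_t == 0 & abs(thc) < 40 * pi / 180 &
                    mesh$phi_ab > 0.15 & mesh$phi_ab < 0.85)
    id <- pick_nodes(cand, cts["septum"], "septal")
    pts <- rbind(pts, mesh$nodes[id, , drop = FALSE])
    atv <- c(atv, psi$psi[id]); reg <- c(reg, rep("septum", length(id)))
  }
  if (cts["cs"] > 0) {
    acc <- veins$accessible
    if (nrow(acc) < cts["cs"]) stop("requested more cs points than accessible vein sites")
    rows <- sample(nrow(acc), cts["cs"])
    p <- as.matrix(acc[rows, c("x", "y", "z")])
    pts <- rbind(pts, p)
    atv <- c(atv, interp_nodal(mesh, psi$psi, p))
    reg <- c(reg, rep("cs", nrow(p)))
  }
  if (cts["lateral"] > 0) {
    cand <- which(mesh$phi_t == 1 & abs(abs(thc) - pi) < 60 * pi / 180 &
                    mesh$phi_ab > 0.1 & mesh$phi_ab < 0.9)
    id <- pick_nodes(cand, cts["lateral"], "lateral")
    pts <- rbind(pts, mesh$nodes[id, , drop = FALSE])
    atv <- c(atv, psi$psi[id]); reg <- c(reg, rep("lateral", length(id)))
  }

  if (noise_sd > 0) {
    n <- length(atv)
    noise <- stats::rnorm(n, 0, noise_sd)
    # truncate at +-3 sd by redrawing
    while (any(abs(noise) > 3 * noise_sd)) {
      bad <- abs(noise) > 3 * noise_sd
      noise[bad] <- stats::rnorm(sum(bad), 0, noise_sd)
    }
    atv <- pmax(atv + noise, 0)
  }
  eams_cloud(pts, atv, reg)
}

# Rigid (rotation + translation) least-squares fit of 3 matched point pairs
# (Kabsch). `from`, `to`: 3 x 3 matrices, one pair per row.
kabsch3 <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  A <- sweep(from, 2, cf); B <- sweep(to, 2, ct)
  # collinearity check
  n1 <- rowcross(matrix(A[2, ] - A[1, ], 1), matrix(A[3, ] - A[1, ], 1))
  if (rownorm(n1) < 1e-8 * max(rownorm(matrix(A[2, ] - A[1, ], 1)), 1))
    stop("degenerate registration: reference points are collinear")
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = ct - as.numeric(R %*% cf))
}

#' Align an EAMS cloud to the LV geometry
#'
#' Three steps: (i) three matched reference point pairs are taken as given;
#' (ii) the rigid rotation + translation minimizing the squared distance over
#' the pairs is applied to the whole cloud; (iii) every point is projected to
#' its nearest point on the LV surface. Activation times are unchanged.
#'
#' @param cloud an `eams_cloud` in the mapping-system frame.
#' @param mesh an `lv_mesh`.
#' @param ref_cloud,ref_mesh matched reference points (3 x 3 matrices): three
#'   non-collinear points in the cloud frame and their geometric counterparts.
#' @return The aligned `eams_cloud` (all points on surface facets).
#' @export
align_eams <- function(cloud, mesh, ref_cloud, ref_mesh) {
  ref_cloud <- matrix(ref_cloud, 3, 3)
  ref_mesh <- matrix(ref_mesh, 3, 3)
  tr <- kabsch3(ref_cloud, ref_mesh)
  moved <- t(tr$R %*% t(cloud$points)) + matrix(tr$t, nrow(cloud$points), 3, byrow = TRUE)
  proj <- project_to_surface(mesh, moved)
  eams_cloud(proj, cloud$at, cloud$region)
}
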