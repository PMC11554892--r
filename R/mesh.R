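# Synthetic left-ventricle geometry: truncated-ellipsoid hexahedral shell with
# analytic normalized coordinates (transmural phi_t, apicobasal phi_ab,
# circumferential theta).
#
# Construction frame: the endocardial and epicardial ellipsoids share a centre;
# the polar angle u is measured from the apex (u = 0) and the base is the plane
# cutting the endocardial ellipsoid at angle `base_angle`. After construction
# the mesh is shifted so the epicardial apex sits at the origin with the long
# axis along +z; theta = 0 is the mid-septum (+x), theta = pi the lateral wall.

#' Build a synthetic truncated-ellipsoid LV mesh
#'
#' Generates a structured hexahedral shell between two confocal-centre
#' ellipsoids, truncated at the base plane and (by a small hole of radius
#' `apex_hole`) near the apex so that every hexahedron is non-degenerate.
#' Normalized coordinates are computed analytically from the parameterization.
#'
#' @param a_endo,b_endo short endocardial semi-axes (mm).
#' @param c_endo long endocardial semi-axis (mm).
#' @param thickness wall thickness added to every semi-axis (mm).
#' @param base_angle polar angle (rad, from the apex) at which the endocardial
#'   ellipsoid meets the base plane.
#' @param target_h target edge length (mm); controls the structured resolution.
#' @param apex_hole radius (mm) of the small apical opening that keeps the
#'   structured grid non-degenerate.
#' @return An object of class `lv_mesh` with fields `nodes` (n x 3, mm),
#'   `elems` (m x 8), `phi_t`, `phi_ab`, `theta` (per node), boundary face
#'   tables, per-element volumes and centroids, and the generating parameters.
#' @export
build_lv_mesh <- function(a_endo = 31.5, b_endo = 31.5, c_endo = 68,
                          thickness = 9.5, base_angle = 1.833,
                          target_h = 3, apex_hole = 2.5) {
  if (thickness <= 0) stop("degenerate geometry: wall thickness must be > 0")
  if (target_h <= 0) stop("target edge length must be > 0")
  if (base_angle <= pi / 2 || base_angle >= pi)
    stop("base_angle must lie in (pi/2, pi)")

  a_epi <- a_endo + thickness
  b_epi <- b_endo + thickness
  c_epi <- c_endo + thickness

  # Resolution from the target edge length
  nt <- max(2L, as.integer(round(thickness / target_h)))
  circ <- 2 * pi * (a_endo + b_endo + thickness) / 2          # mean circumference
  nc <- 12L * max(1L, as.integer(round(circ / (12 * target_h))))
  merid <- c_endo * (base_angle - apex_hole / a_endo)          # meridian arc (approx)
  nab <- max(4L, as.integer(round(merid / target_h)))

  build_lv_mesh_structured(a_endo, b_endo, c_endo, thickness, base_angle,
                           apex_hole, nt, nab, nc, target_h)
}

# Deterministic builder at explicit structured resolution (used by refinement).
build_lv_mesh_structured <- function(a_endo, b_endo, c_endo, thickness,
                                     base_angle, apex_hole, nt, nab, nc,
                                     target_h = NA_real_) {
  a_epi <- a_endo + thickness
  b_epi <- b_endo + thickness
  c_epi <- c_endo + thickness
  z_base <- -c_endo * cos(base_angle)     # construction-frame base plane height

  # Shells: transmural parameter s in [0,1]
  s_vals <- seq(0, 1, length.out = nt + 1L)
  ab_vals <- seq(0, 1, length.out = nab + 1L)
  th_vals <- 2 * pi * (seq_len(nc) - 1L) / nc

  shell_axes <- function(s) {
    c(a_endo + thickness * s, b_endo + thickness * s, c_endo + thickness * s)
  }

  n_per_shell <- (nab + 1L) * nc
  n_nodes <- (nt + 1L) * n_per_shell
  nodes <- matrix(0, n_nodes, 3)
  phi_t <- numeric(n_nodes)
  phi_ab <- numeric(n_nodes)
  theta <- numeric(n_nodes)
  u_node <- numeric(n_nodes)

  nid <- function(it, j, i) {          # it in 0..nt, j in 0..nab, i in 0..nc-1
    it * n_per_shell + j * nc + i + 1L
  }

  for (it in 0:nt) {
    ax <- shell_axes(s_vals[it + 1L])
    a <- ax[1]; b <- ax[2]; cc <- ax[3]
    u_apex <- asin(min(1, apex_hole / a))
    u_base <- acos(max(-1, min(1, -z_base / cc)))
    for (j in 0:nab) {
      u <- u_apex + ab_vals[j + 1L] * (u_base - u_apex)
      idx <- nid(it, j, 0:(nc - 1L))
      nodes[idx, 1] <- a * sin(u) * cos(th_vals)
      nodes[idx, 2] <- b * sin(u) * sin(th_vals)
      nodes[idx, 3] <- -cc * cos(u) + c_epi
      phi_t[idx] <- s_vals[it + 1L]
      phi_ab[idx] <- ab_vals[j + 1L]
      theta[idx] <- th_vals
      u_node[idx] <- u
    }
  }

  # Hexahedra (VTK ordering: endo quad then epi quad, consistent orientation)
  n_elems <- nt * nab * nc
  elems <- matrix(0L, n_elems, 8)
  k <- 0L
  ip1 <- c(2:nc, 1L) - 1L     # periodic next circumferential index
  for (it in 0:(nt - 1L)) {
    for (j in 0:(nab - 1L)) {
      i <- 0:(nc - 1L)
      rows <- k + seq_len(nc)
      elems[rows, ] <- cbind(nid(it, j, i),      nid(it, j, ip1[i + 1L]),
                             nid(it, j + 1L, ip1[i + 1L]), nid(it, j + 1L, i),
                             nid(it + 1L, j, i), nid(it + 1L, j, ip1[i + 1L]),
                             nid(it + 1L, j + 1L, ip1[i + 1L]), nid(it + 1L, j + 1L, i))
      k <- k + nc
    }
  }

  vol <- hex_volumes(nodes, elems)
  if (any(vol <= 0)) {
    # flip transmural order if orientation came out negative
    elems <- elems[, c(5:8, 1:4)]
    vol <- hex_volumes(nodes, elems)
  }
  if (any(vol <= 0)) stop("mesh generation produced inverted elements")

  centroid <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] + nodes[elems[, 3], ] +
                 nodes[elems[, 4], ] + nodes[elems[, 5], ] + nodes[elems[, 6], ] +
                 nodes[elems[, 7], ] + nodes[elems[, 8], ]) / 8

  # Boundary faces (quads) with tags
  faces <- list()
  # endocardium: it = 0 sheet, faces of elements it=0 on their endo side
  endo_elems <- which(rep(rep(0:(nt - 1L), each = nab), each = nc) == 0L)
  faces$endocardium <- elems[endo_elems, c(1, 2, 3, 4), drop = FALSE]
  epi_elems <- which(rep(rep(0:(nt - 1L), each = nab), each = nc) == nt - 1L)
  faces$epicardium <- elems[epi_elems, c(5, 6, 7, 8), drop = FALSE]
  j_of_elem <- rep(rep(rep(0:(nab - 1L), each = nc), times = nt), times = 1L)
  base_elems <- which(j_of_elem == nab - 1L)
  faces$base <- elems[base_elems, c(4, 3, 7, 8), drop = FALSE]
  apex_elems <- which(j_of_elem == 0L)
  faces$apex <- elems[apex_elems, c(1, 2, 6, 5), drop = FALSE]

  boundary <- do.call(rbind, faces)
  boundary_tag <- rep(c("endocardium", "epicardium", "base", "apex"),
                      vapply(faces, nrow, 1L))

  edges <- rbind(nodes[elems[, 2], ] - nodes[elems[, 1], ],
                 nodes[elems[, 4], ] - nodes[elems[, 1], ],
                 nodes[elems[, 5], ] - nodes[elems[, 1], ])
  mean_h <- mean(rownorm(edges))

  structure(list(
    nodes = nodes, elems = elems,
    phi_t = phi_t, phi_ab = phi_ab, theta = theta, u = u_node,
    boundary = boundary, boundary_tag = boundary_tag,
    elem_volume = vol, elem_centroid = centroid,
    mean_edge = mean_h,
    dims = c(nt = nt, nab = nab, nc = nc),
    params = list(a_endo = a_endo, b_endo = b_endo, c_endo = c_endo,
                  thickness = thickness, base_angle = base_angle,
                  apex_hole = apex_hole, target_h = target_h)
  ), class = "lv_mesh")
}

#' Refine an LV mesh by structured splitting
#'
#' Doubles (`factor = 2`) the structured resolution in every parametric
#' direction, reproducing the nested coarse/fine mesh pair used for the
#' mechanics and electrophysiology problems.
#'
#' @param mesh an `lv_mesh`.
#' @param factor integer split factor per parametric axis.
#' @return A finer `lv_mesh` nested (in the generating parameters) in `mesh`.
#' @export
refine_lv_mesh <- function(mesh, factor = 2L) {
  stopifnot(inherits(mesh, "lv_mesh"), factor >= 2)
  d <- mesh$dims
  p <- mesh$params
  build_lv_mesh_structured(p$a_endo, p$b_endo, p$c_endo, p$thickness,
                           p$base_angle, p$apex_hole,
                           as.integer(d["nt"] * factor),
                           as.integer(d["nab"] * factor),
                           as.integer(d["nc"] * factor),
                           target_h = if (is.na(p$target_h)) NA_real_ else p$target_h / factor)
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat("LV hexahedral mesh\n")
  cat(sprintf("  nodes: %d   elements: %d   mean edge: %.2f mm\n",
              nrow(x$nodes), nrow(x$elems), x$mean_edge))
  cat(sprintf("  structured dims (nt x nab x nc): %d x %d x %d\n",
              x$dims["nt"], x$dims["nab"], x$dims["nc"]))
  cat(sprintf("  cavity volume: %.1f ml   wall volume: %.1f ml\n",
              cavity_volume(x) / 1000, sum(x$elem_volume) / 1000))
  invisible(x)
}

# Signed volumes of hexahedra via the 6-tet decomposition around diagonal 1-7.
hex_volumes <- function(nodes, elems) {
  tv <- function(i, j, k, l) {
    a <- nodes[elems[, j], , drop = FALSE] - nodes[elems[, i], , drop = FALSE]
    b <- nodes[elems[, k], , drop = FALSE] - nodes[elems[, i], , drop = FALSE]
    cc <- nodes[elems[, l], , drop = FALSE] - nodes[elems[, i], , drop = FALSE]
    rowdot(a, rowcross(b, cc)) / 6
  }
  tv(1, 2, 3, 7) + tv(1, 3, 4, 7) + tv(1, 4, 8, 7) +
    tv(1, 8, 5, 7) + tv(1, 5, 6, 7) + tv(1, 6, 2, 7)
}

# Standard 6-tet split of every hex (shared diagonal node1-node7).
hex_to_tets <- function(elems) {
  pat <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
               c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  m <- nrow(elems)
  tets <- matrix(0L, 6L * m, 4)
  for (q in 1:6) {
    tets[seq.int(q, by = 6L, length.out = m), ] <- elems[, pat[q, ], drop = FALSE]
  }
  list(tets = tets, elem_of_tet = rep(seq_len(m), each = 6L))
}

#' Cavity volume enclosed by the endocardial surface
#'
#' Closes the endocardium with flat base and apex caps and evaluates the
#' divergence-theorem volume of the enclosed region.
#'
#' @param mesh an `lv_mesh`.
#' @return Cavity volume in mm^3.
#' @export
cavity_volume <- function(mesh) {
  quads <- mesh$boundary[mesh$boundary_tag == "endocardium", , drop = FALSE]
  tris <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  # cap rings: endocardial base ring (phi_t = 0, phi_ab = 1) and apex ring
  endo_nodes <- which(mesh$phi_t == 0)
  base_ring <- endo_nodes[mesh$phi_ab[endo_nodes] == 1]
  apex_ring <- endo_nodes[mesh$phi_ab[endo_nodes] == 0]
  ring_tris <- function(ring) {
    ring <- ring[order(mesh$theta[ring])]
    ctr <- colMeans(mesh$nodes[ring, , drop = FALSE])
    nn <- length(ring)
    list(ring = ring, ctr = ctr,
         tri = cbind(ring, ring[c(2:nn, 1)]))
  }
  vol_tris <- sum(rowdot(mesh$nodes[tris[, 1], , drop = FALSE],
                         rowcross(mesh$nodes[tris[, 2], , drop = FALSE],
                                  mesh$nodes[tris[, 3], , drop = FALSE]))) / 6
  cap_vol <- function(ring) {
    rt <- ring_tris(ring)
    p1 <- mesh$nodes[rt$tri[, 1], , drop = FALSE]
    p2 <- mesh$nodes[rt$tri[, 2], , drop = FALSE]
    p3 <- matrix(rt$ctr, nrow(rt$tri), 3, byrow = TRUE)
    sum(rowdot(p1, rowcross(p2, p3))) / 6
  }
  abs(vol_tris + cap_vol(base_ring) + cap_vol(apex_ring))
}

# ---- point location & interpolation -----------------------------------------

# Trilinear shape functions on the reference cube [-1,1]^3 in VTK hex ordering.
hex_shape <- function(xi) {
  r <- xi[, 1]; s <- xi[, 2]; t <- xi[, 3]
  cbind((1 - r) * (1 - s) * (1 - t), (1 + r) * (1 - s) * (1 - t),
        (1 + r) * (1 + s) * (1 - t), (1 - r) * (1 + s) * (1 - t),
        (1 - r) * (1 - s) * (1 + t), (1 + r) * (1 - s) * (1 + t),
        (1 + r) * (1 + s) * (1 + t), (1 - r) * (1 + s) * (1 + t)) / 8
}

# Inverse trilinear map of one point in one hex (Newton); returns xi and
# convergence/containment info.
hex_invert <- function(X, p, tol = 1e-10, maxit = 30L) {
  xi <- c(0, 0, 0)
  for (it in seq_len(maxit)) {
    r <- xi[1]; s <- xi[2]; t <- xi[3]
    N <- hex_shape(matrix(xi, 1))[1, ]
    dN_dr <- c(-(1 - s) * (1 - t), (1 - s) * (1 - t), (1 + s) * (1 - t), -(1 + s) * (1 - t),
               -(1 - s) * (1 + t), (1 - s) * (1 + t), (1 + s) * (1 + t), -(1 + s) * (1 + t)) / 8
    dN_ds <- c(-(1 - r) * (1 - t), -(1 + r) * (1 - t), (1 + r) * (1 - t), (1 - r) * (1 - t),
               -(1 - r) * (1 + t), -(1 + r) * (1 + t), (1 + r) * (1 + t), (1 - r) * (1 + t)) / 8
    dN_dt <- c(-(1 - r) * (1 - s), -(1 + r) * (1 - s), -(1 + r) * (1 + s), -(1 - r) * (1 + s),
               (1 - r) * (1 - s), (1 + r) * (1 - s), (1 + r) * (1 + s), (1 - r) * (1 + s)) / 8
    res <- as.numeric(N %*% X) - p
    if (sqrt(sum(res^2)) < tol) break
    J <- rbind(as.numeric(dN_dr %*% X), as.numeric(dN_ds %*% X), as.numeric(dN_dt %*% X))
    step <- tryCatch(solve(t(J), res), error = function(e) rep(0, 3))
    xi <- xi - step
    xi <- pmax(pmin(xi, 1.5), -1.5)
  }
  list(xi = xi, inside = all(abs(xi) <= 1 + 1e-6))
}

# Locate points in the mesh: nearest-centroid candidates then inverse mapping.
# Returns element index and trilinear weights per point.
locate_points <- function(mesh, pts, k_candidates = 12L) {
  pts <- matrix(pts, ncol = 3)
  n <- nrow(pts)
  elem <- integer(n)
  wts <- matrix(0, n, 8)
  cen <- mesh$elem_centroid
  for (q in seq_len(n)) {
    d2 <- (cen[, 1] - pts[q, 1])^2 + (cen[, 2] - pts[q, 2])^2 + (cen[, 3] - pts[q, 3])^2
    cand <- order(d2)[seq_len(min(k_candidates, nrow(cen)))]
    best <- NULL; best_pen <- Inf
    for (e in cand) {
      X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
      inv <- hex_invert(X, pts[q, ])
      pen <- max(0, max(abs(inv$xi)) - 1)
      if (pen < best_pen) {
        best_pen <- pen
        best <- list(e = e, xi = pmax(pmin(inv$xi, 1), -1))
        if (inv$inside) break
      }
    }
    elem[q] <- best$e
    wts[q, ] <- hex_shape(matrix(best$xi, 1))
  }
  list(elem = elem, weights = wts)
}

# Interpolate a nodal field at arbitrary points (trilinear in the containing hex,
# clamped local coordinates for points marginally outside, e.g. surface points).
interp_nodal <- function(mesh, field, pts) {
  loc <- locate_points(mesh, pts)
  vals <- numeric(length(loc$elem))
  for (q in seq_along(vals)) {
    vals[q] <- sum(loc$weights[q, ] * field[mesh$elems[loc$elem[q], ]])
  }
  vals
}

# ---- surface utilities ------------------------------------------------------

# Closest point on a triangle (vectorized over triangles for one query point).
closest_on_triangles <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A; ap <- matrix(p, nrow(A), 3, byrow = TRUE) - A
  d1 <- rowdot(ab, ap); d2 <- rowdot(ac, ap)
  bp <- matrix(p, nrow(A), 3, byrow = TRUE) - B
  d3 <- rowdot(ab, bp); d4 <- rowdot(ac, bp)
  cp <- matrix(p, nrow(A), 3, byrow = TRUE) - C
  d5 <- rowdot(ab, cp); d6 <- rowdot(ac, cp)

  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  out <- A + v * ab + w * ac

  # vertex / edge regions
  reg_a <- d1 <= 0 & d2 <= 0
  reg_b <- d3 >= 0 & d4 <= d3
  reg_c <- d6 >= 0 & d5 <= d6
  reg_ab <- !reg_a & !reg_b & vc <= 0 & d1 >= 0 & d3 <= 0
  reg_ac <- !reg_a & !reg_c & vb <= 0 & d2 >= 0 & d6 <= 0
  reg_bc <- !reg_b & !reg_c & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0

  t_ab <- ifelse(d1 - d3 != 0, d1 / (d1 - d3), 0)
  t_ac <- ifelse(d2 - d6 != 0, d2 / (d2 - d6), 0)
  t_bc <- ifelse((d4 - d3) + (d5 - d6) != 0, (d4 - d3) / ((d4 - d3) + (d5 - d6)), 0)

  out[reg_bc, ] <- B[reg_bc, , drop = FALSE] +
    t_bc[reg_bc] * (C[reg_bc, , drop = FALSE] - B[reg_bc, , drop = FALSE])
  out[reg_ac, ] <- A[reg_ac, , drop = FALSE] + t_ac[reg_ac] * ac[reg_ac, , drop = FALSE]
  out[reg_ab, ] <- A[reg_ab, , drop = FALSE] + t_ab[reg_ab] * ab[reg_ab, , drop = FALSE]
  out[reg_c, ] <- C[reg_c, , drop = FALSE]
  out[reg_b, ] <- B[reg_b, , drop = FALSE]
  out[reg_a, ] <- A[reg_a, , drop = FALSE]
  out
}

# Surface triangle soup for a tag set (default: whole LV surface).
surface_triangles <- function(mesh, tags = c("endocardium", "epicardium", "base", "apex")) {
  keep <- mesh$boundary_tag %in% tags
  quads <- mesh$boundary[keep, , drop = FALSE]
  tris <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  list(A = mesh$nodes[tris[, 1], , drop = FALSE],
       B = mesh$nodes[tris[, 2], , drop = FALSE],
       C = mesh$nodes[tris[, 3], , drop = FALSE],
       tri = tris)
}

# Project points onto the mesh surface (nearest point on any facet).
project_to_surface <- function(mesh, pts, tags = c("endocardium", "epicardium", "base", "apex"),
                               k_candidates = 60L) {
  st <- surface_triangles(mesh, tags)
  cen <- (st$A + st$B + st$C) / 3
  pts <- matrix(pts, ncol = 3)
  out <- pts
  for (q in seq_len(nrow(pts))) {
    d2 <- (cen[, 1] - pts[q, 1])^2 + (cen[, 2] - pts[q, 2])^2 + (cen[, 3] - pts[q, 3])^2
    cand <- order(d2)[seq_len(min(k_candidates, nrow(cen)))]
    cl <- closest_on_triangles(pts[q, ], st$A[cand, , drop = FALSE],
                               st$B[cand, , drop = FALSE], st$C[cand, , drop = FALSE])
    dd <- rowSums((cl - matrix(pts[q, ], length(cand), 3, byrow = TRUE))^2)
    out[q, ] <- cl[which.min(dd), ]
  }
  out
}

# Analytic point on a shell surface of the generating ellipsoid family.
# s = 0 endo, s = 1 epi; phi_ab in [0,1]; theta in [0, 2pi).
shell_point <- function(mesh, s, phi_ab, theta) {
  p <- mesh$params
  a <- p$a_endo + p$thickness * s
  b <- p$b_endo + p$thickness * s
  cc <- p$c_endo + p$thickness * s
  z_base <- -p$c_endo * cos(p$base_angle)
  u_apex <- asin(pmin(1, p$apex_hole / a))
  u_base <- acos(pmax(-1, pmin(1, -z_base / cc)))
  u <- u_apex + phi_ab * (u_base - u_apex)
  cbind(a * sin(u) * cos(theta), b * sin(u) * sin(theta),
        -cc * cos(u) + (p$c_endo + p$thickness))
}

# Analytic truncated-ellipsoid cap volume (apex pole to the base plane), used
# as the closed-form oracle for the generated cavity.
ellipsoid_cap_volume <- function(a, b, cc, base_angle) {
  z_b <- -cc * cos(base_angle)
  pi * a * b * (z_b - z_b^3 / (3 * cc^2) + 2 * cc / 3)
}

#' Build a structured box mesh
#'
#' Axis-aligned hexahedral box, used as the analytic benchmark geometry for
#' the eikonal solver (planar/spherical front solutions are closed-form
#' there).
#'
#' @param lx,ly,lz box edge lengths (mm).
#' @param h target edge length (mm).
#' @return An `lv_mesh`-compatible object (no shell parameterization fields).
#' @export
build_box_mesh <- function(lx = 20, ly = 5, lz = 5, h = 1) {
  nx <- max(1L, as.integer(round(lx / h)))
  ny <- max(1L, as.integer(round(ly / h)))
  nz <- max(1L, as.integer(round(lz / h)))
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  zs <- seq(0, lz, length.out = nz + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L)
  idx <- expand.grid(i = 1:nx, j = 1:ny, k = 1:nz)
  elems <- cbind(nid(idx$i, idx$j, idx$k), nid(idx$i + 1L, idx$j, idx$k),
                 nid(idx$i + 1L, idx$j + 1L, idx$k), nid(idx$i, idx$j + 1L, idx$k),
                 nid(idx$i, idx$j, idx$k + 1L), nid(idx$i + 1L, idx$j, idx$k + 1L),
                 nid(idx$i + 1L, idx$j + 1L, idx$k + 1L), nid(idx$i, idx$j + 1L, idx$k + 1L))
  vol <- hex_volumes(nodes, elems)
  centroid <- (nodes[elems[, 1], ] + nodes[elems[, 7], ]) / 2
  structure(list(nodes = nodes, elems = elems, elem_volume = vol,
                 elem_centroid = centroid, mean_edge = mean(c(lx / nx, ly / ny, lz / nz)),
                 dims = c(nx = nx, ny = ny, nz = nz)),
            class = "lv_mesh")
}

#' Uniform fibre field
#'
#' Constant orthonormal triad on every element (benchmark geometries).
#'
#' @param n_elems number of elements.
#' @param f,s fibre and sheet directions (normalized and orthogonalized).
#' @return A `fiber_field`.
#' @export
uniform_fibers <- function(n_elems, f = c(1, 0, 0), s = c(0, 1, 0)) {
  f <- f / sqrt(sum(f^2))
  s <- s - sum(s * f) * f
  s <- s / sqrt(sum(s^2))
  n <- c(f[2] * s[3] - f[3] * s[2], f[3] * s[1] - f[1] * s[3], f[1] * s[2] - f[2] * s[1])
  structure(list(f = matrix(f, n_elems, 3, byrow = TRUE),
                 s = matrix(s, n_elems, 3, byrow = TRUE),
                 n = matrix(n, n_elems, 3, byrow = TRUE)), class = "fiber_field")
}
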