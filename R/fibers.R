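# Rule-based myocardial fibre architecture, AHA-17 segmentation and bullseye
# fibrosis fields on the synthetic LV mesh.

#' Generate rule-based fibre, sheet and normal directions
#'
#' Per-element orthonormal microstructure triads (f, s, n). The helix angle of
#' the fibre direction rotates linearly across the wall from `+alpha_endo` at
#' the endocardium to `-alpha_epi` at the epicardium (the conventional
#' transmural rotation); the sheet angle rotates likewise between the `beta`
#' values. The local circumferential/longitudinal/transmural frame is obtained
#' analytically from the ellipsoid parameterization of the mesh.
#'
#' @param mesh an `lv_mesh`.
#' @param alpha_epi,alpha_endo fibre helix boundary angles (degrees).
#' @param beta_epi,beta_endo sheet boundary angles (degrees).
#' @return An object of class `fiber_field` with unit matrices `f`, `s`, `n`
#'   (elements x 3).
#' @export
generate_fibers <- function(mesh, alpha_epi = 60, alpha_endo = 60,
                            beta_epi = 20, beta_endo = 20) {
  el <- mesh$elems
  # element-centroid parametric coordinates
  phi_t <- rowMeans(matrix(mesh$phi_t[el], ncol = 8))
  u <- rowMeans(matrix(mesh$u[el], ncol = 8))
  # circular mean of theta (elements straddle the 0/2pi seam)
  th_s <- rowMeans(matrix(sin(mesh$theta[el]), ncol = 8))
  th_c <- rowMeans(matrix(cos(mesh$theta[el]), ncol = 8))
  th <- atan2(th_s, th_c)

  p <- mesh$params
  a <- p$a_endo + p$thickness * phi_t
  b <- p$b_endo + p$thickness * phi_t
  cc <- p$c_endo + p$thickness * phi_t

  e_th <- cbind(-a * sin(u) * sin(th), b * sin(u) * cos(th), 0)
  e_u <- cbind(a * cos(u) * cos(th), b * cos(u) * sin(th), cc * sin(u))

  c_dir <- rowunit(e_th)                                    # circumferential
  l_dir <- rowunit(e_u - rowdot(e_u, c_dir) * c_dir)        # longitudinal (to base)
  t_dir <- rowcross(c_dir, l_dir)                           # transmural (outward)

  alpha <- (alpha_endo + (-alpha_epi - alpha_endo) * phi_t) * pi / 180
  beta <- (beta_endo + (-beta_epi - beta_endo) * phi_t) * pi / 180

  f <- cos(alpha) * c_dir + sin(alpha) * l_dir
  g <- t_dir - rowdot(t_dir, f) * f                         # ~ t_dir (already _|_ f)
  g <- rowunit(g)
  s <- cos(beta) * g + sin(beta) * rowcross(f, g)
  n <- rowcross(f, s)

  structure(list(f = f, s = s, n = n), class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  res <- fiber_orthonormality_residual(x)
  cat(sprintf("Fibre field: %d element triads, max orthonormality residual %.2e\n",
              nrow(x$f), res))
  invisible(x)
}

#' Maximum orthonormality residual of a fibre field
#' @param fibers a `fiber_field`.
#' @return Largest deviation of any |f|, |s|, |n| from 1 or pairwise dot from 0.
#' @export
fiber_orthonormality_residual <- function(fibers) {
  max(abs(rownorm(fibers$f) - 1), abs(rownorm(fibers$s) - 1),
      abs(rownorm(fibers$n) - 1),
      abs(rowdot(fibers$f, fibers$s)), abs(rowdot(fibers$f, fibers$n)),
      abs(rowdot(fibers$s, fibers$n)))
}

#' AHA 17-segment labelling
#'
#' Assigns every element an American Heart Association bullseye segment from
#' its centroid normalized coordinates: basal ring (segments 1-6) for
#' phi_ab > 2/3, mid ring (7-12) for 1/3-2/3, apical ring (13-16, four
#' sectors) for 1/9-1/3, and the apical cap (17) below 1/9. theta = 0 is the
#' mid-septum, theta = pi the lateral wall.
#'
#' @param mesh an `lv_mesh`.
#' @return Integer vector of segment ids (1..17), one per element.
#' @export
aha_segments <- function(mesh) {
  el <- mesh$elems
  phi_ab <- rowMeans(matrix(mesh$phi_ab[el], ncol = 8))
  th_s <- rowMeans(matrix(sin(mesh$theta[el]), ncol = 8))
  th_c <- rowMeans(matrix(cos(mesh$theta[el]), ncol = 8))
  th <- atan2(th_s, th_c) * 180 / pi      # (-180, 180], 0 = mid-septum

  seg <- integer(length(th))
  ring <- ifelse(phi_ab > 2 / 3, 1L, ifelse(phi_ab > 1 / 3, 2L,
                 ifelse(phi_ab > 1 / 9, 3L, 4L)))
  # basal/mid sector ids
  sec <- integer(length(th))
  sec[th > -60 & th <= 0] <- 2L       # anteroseptal
  sec[th > 0 & th <= 60] <- 3L        # inferoseptal
  sec[th > 60 & th <= 120] <- 4L      # inferior
  sec[th > 120] <- 5L                 # inferolateral
  sec[th <= -120] <- 6L               # anterolateral
  sec[th > -120 & th <= -60] <- 1L    # anterior
  # apical 90-degree sectors: septal centred on theta = 0
  ap <- integer(length(th))
  ap[th > -45 & th <= 45] <- 14L      # septal
  ap[th > 45 & th <= 135] <- 15L      # inferior
  ap[th > 135 | th <= -135] <- 16L    # lateral
  ap[th > -135 & th <= -45] <- 13L    # anterior

  seg[ring == 1L] <- sec[ring == 1L]
  seg[ring == 2L] <- sec[ring == 2L] + 6L
  seg[ring == 3L] <- ap[ring == 3L]
  seg[ring == 4L] <- 17L
  seg
}

#' Build a per-element fibrosis field from a bullseye
#'
#' @param mesh an `lv_mesh`.
#' @param aha integer AHA segment per element (from [aha_segments()]).
#' @param bullseye named list/vector mapping segment id (1..17) to the fibrosis
#'   factor z in `[0, 1]` (z = 1 healthy). Segments not named stay healthy.
#' @return An object of class `fibrosis_field`: per-element `z` plus the source
#'   bullseye.
#' @export
make_fibrosis_field <- function(mesh, aha, bullseye = list()) {
  z <- rep(1, nrow(mesh$elems))
  if (length(bullseye)) {
    ids <- as.integer(names(bullseye))
    vals <- as.numeric(unlist(bullseye))
    if (any(is.na(ids)) || any(!(ids %in% 1:17)))
      stop("bullseye keys must be AHA segment ids in 1..17")
    if (any(vals < 0 | vals > 1))
      stop("bullseye z values must lie in [0, 1]")
    for (k in seq_along(ids)) z[aha == ids[k]] <- vals[k]
  }
  structure(list(z = z, bullseye = bullseye), class = "fibrosis_field")
}
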