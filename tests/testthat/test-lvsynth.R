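# Synthetic anatomy: mesh generation, fibres, AHA segmentation, fibrosis,
# veins, EAMS synthesis and alignment.

test_that("generated LV mesh is valid and matches the analytic cavity volume", {
  mesh <- test_mesh()
  expect_true(all(mesh$elem_volume > 0))
  expect_true(all(mesh$phi_t >= 0 & mesh$phi_t <= 1))
  expect_true(all(mesh$phi_ab >= 0 & mesh$phi_ab <= 1))
  p <- mesh$params
  v_analytic <- ellipsoid_cap_volume(p$a_endo, p$b_endo, p$c_endo, p$base_angle)
  expect_lt(abs(cavity_volume(mesh) - v_analytic) / v_analytic, 0.02)
  expect_error(build_lv_mesh(thickness = 0), "thickness")
})

test_that("structured refinement nests the coarse mesh and shrinks edges", {
  coarse <- build_lv_mesh(target_h = 7)
  fine <- refine_lv_mesh(coarse, 2L)
  expect_equal(unname(fine$dims), unname(2L * coarse$dims))
  expect_lt(fine$mean_edge, 0.6 * coarse$mean_edge)
  # coarse nodes are a subset of fine nodes (nested generation parameters)
  i <- 10L
  d <- sqrt(rowSums((fine$nodes - matrix(coarse$nodes[i, ], nrow(fine$nodes), 3,
                                         byrow = TRUE))^2))
  expect_lt(min(d), 1e-9)
})

test_that("fibre triads follow the transmural helix rule", {
  mesh <- build_lv_mesh(target_h = 3.2)      # 3 transmural layers: a true mid-wall
  # zero angles: purely circumferential fibres
  f0 <- generate_fibers(mesh, alpha_epi = 0, alpha_endo = 0,
                        beta_epi = 0, beta_endo = 0)
  # circumferential means no z-component and tangent to the wall
  expect_lt(max(abs(f0$f[, 3])), 1e-8)
  # default angles: orthonormal within 1e-8 and helix sign flips across wall
  fb <- generate_fibers(mesh)
  expect_lt(fiber_orthonormality_residual(fb), 1e-8)
  phi_t <- rowMeans(matrix(mesh$phi_t[mesh$elems], ncol = 8))
  endo <- which(phi_t < 0.3); epi <- which(phi_t > 0.7)
  expect_gt(mean(fb$f[endo, 3] > 0), 0.95)   # +60 deg at endo climbs to base
  expect_gt(mean(fb$f[epi, 3] < 0), 0.95)    # -60 deg at epi descends
  # mid-wall helix angle is the mean of the boundary settings; measure it
  # against a finite-difference local frame (independent of the generator)
  fb2 <- generate_fibers(mesh, alpha_endo = 60, alpha_epi = 0)
  mid <- which(abs(phi_t - 0.5) < 0.05)
  expect_gt(length(mid), 10)
  phi_ab <- rowMeans(matrix(mesh$phi_ab[mesh$elems], ncol = 8))
  th <- atan2(rowMeans(matrix(sin(mesh$theta[mesh$elems]), ncol = 8)),
              rowMeans(matrix(cos(mesh$theta[mesh$elems]), ncol = 8)))
  d <- 1e-4
  sp <- function(s, ab, t) crtsim:::shell_point(mesh, s, ab, t)
  ang <- vapply(mid, function(e) {
    c_fd <- sp(0.5, phi_ab[e], th[e] + d) - sp(0.5, phi_ab[e], th[e] - d)
    l_fd <- sp(0.5, phi_ab[e] + d, th[e]) - sp(0.5, phi_ab[e] - d, th[e])
    c_fd <- c_fd / sqrt(sum(c_fd^2)); l_fd <- l_fd / sqrt(sum(l_fd^2))
    atan2(sum(fb2$f[e, ] * l_fd), sum(fb2$f[e, ] * c_fd)) * 180 / pi
  }, numeric(1))
  expect_lt(abs(mean(ang) - 30), 3)          # (60 + (-0))/2 at phi_t = 0.5
})

test_that("AHA labelling partitions the wall into 17 positive-volume segments", {
  mesh <- test_mesh()
  aha <- aha_segments(mesh)
  expect_setequal(unique(aha), 1:17)
  vols <- tapply(mesh$elem_volume, aha, sum)
  expect_true(all(vols > 0))
  # pure function of (phi_ab, theta): recomputation is identical
  expect_identical(aha, aha_segments(mesh))
})

test_that("bullseye fibrosis fields map segments exactly", {
  mesh <- test_mesh()
  aha <- aha_segments(mesh)
  f_empty <- make_fibrosis_field(mesh, aha, list())
  expect_true(all(f_empty$z == 1))
  f5 <- make_fibrosis_field(mesh, aha, list(`5` = 0.7))
  expect_true(all(f5$z[aha == 5] == 0.7))
  expect_true(all(f5$z[aha != 5] == 1))
  frac_z <- sum(mesh$elem_volume[f5$z < 1]) / sum(mesh$elem_volume)
  frac_5 <- sum(mesh$elem_volume[aha == 5]) / sum(mesh$elem_volume)
  expect_equal(frac_z, frac_5)
  expect_error(make_fibrosis_field(mesh, aha, list(`3` = 1.2)), "\\[0, 1\\]")
})

test_that("vein splines interpolate cleanly", {
  # collinear points: straight segment, arc length equals chord
  pts <- cbind(seq(0, 10, length.out = 5), 0, 0)
  pl <- fit_vein_spline(pts, step = 2)
  expect_lt(abs(sum(sqrt(rowSums(diff(pl)^2))) - 10) / 10, 0.01)
  expect_equal(pl[1, ], c(0, 0, 0))
  expect_equal(pl[nrow(pl), ], c(10, 0, 0))
  # circle arc of radius 20: radial deviation < 0.2 mm at 2 mm sampling
  th <- seq(0, pi / 2, length.out = 12)
  circ <- cbind(20 * cos(th), 20 * sin(th), 0)
  plc <- fit_vein_spline(circ, step = 2)
  expect_lt(max(abs(sqrt(rowSums(plc^2)) - 20)), 0.2)
  # duplicated consecutive points are dropped before fitting
  dup <- pts[c(1, 1, 2, 3, 3, 4, 5), ]
  expect_silent(pld <- fit_vein_spline(dup, step = 2))
  expect_lt(abs(sum(sqrt(rowSums(diff(pld)^2))) - 10) / 10, 0.01)
  expect_error(fit_vein_spline(pts[1:2, ]), "3")
})

test_that("polyline distance is the exact segment distance", {
  a <- cbind(seq(0, 10, 1), 0, 0)
  expect_equal(polyline_distance(a, a)$max, 0)
  b <- cbind(seq(0, 10, 1), 3.1, 0)
  expect_equal(polyline_distance(a, b)$max, 3.1, tolerance = 1e-12)
  # interior perpendicular projection, not endpoint distance
  seg <- rbind(c(0, 0, 0), c(10, 0, 0))
  p <- rbind(c(5, 2, 0))
  expect_equal(polyline_distance(p, seg)$dist, 2, tolerance = 1e-12)
  expect_error(polyline_distance(a[0, , drop = FALSE], b), "non-empty")
})

test_that("procedural vein trees hug the epicardium deterministically", {
  mesh <- test_mesh()
  v1 <- generate_vein_tree(mesh, seed = 5)
  v2 <- generate_vein_tree(mesh, seed = 5)
  v3 <- generate_vein_tree(mesh, seed = 6)
  expect_identical(v1$branches, v2$branches)
  expect_false(identical(v1$branches, v3$branches))
  expect_lt(vein_surface_distance(mesh, v1), 1.0)
  expect_true(all(diff(v1$accessible$arc[v1$accessible$branch == 1]) > 0))
})

test_that("synthetic EAMS reproduces the truth exactly at zero noise", {
  b <- test_bundle_clean()
  cs <- b$eams_sinus$region == "cs"
  t_interp <- interp_activation(b$psi_sinus, b$mesh,
                                b$eams_sinus$points[cs, , drop = FALSE])
  expect_equal(b$eams_sinus$at[cs], t_interp, tolerance = 1e-9)
  # septal/lateral points are mesh nodes: exact equality
  sep <- b$eams_sinus$region == "septum"
  idx <- apply(b$eams_sinus$points[sep, , drop = FALSE], 1, function(p)
    which.min(rowSums((b$mesh$nodes - matrix(p, nrow(b$mesh$nodes), 3, byrow = TRUE))^2)))
  expect_equal(b$eams_sinus$at[sep], b$psi_sinus$psi[idx], tolerance = 1e-12)
})

test_that("EAMS time noise has the configured spread", {
  b <- test_bundle_clean()
  noisy <- synthesize_eams(b$psi_sinus, b$mesh, b$veins,
                           counts = c(septum = 0, cs = 0, lateral = 200),
                           noise_sd = 0.005, seed = 42)
  idx <- apply(noisy$points, 1, function(p)
    which.min(rowSums((b$mesh$nodes - matrix(p, nrow(b$mesh$nodes), 3, byrow = TRUE))^2)))
  resid <- noisy$at - b$psi_sinus$psi[idx]
  expect_gt(sd(resid), 0.004)
  expect_lt(sd(resid), 0.006)
  expect_lt(max(abs(resid)), 0.0151)   # truncation at 3 sd
  expect_error(synthesize_eams(b$psi_sinus, b$mesh, b$veins,
                               counts = c(septum = 1e5, cs = 0, lateral = 0)),
               "candidate")
})

test_that("EAMS alignment recovers a known rigid transform", {
  b <- test_bundle_clean()
  raw <- b$eams_sinus
  ref0 <- raw$points[c(1, 5, 9), ]
  # put the cloud exactly on the facet surface first
  cl <- align_eams(raw, b$mesh, ref0, ref0)
  # identity pairs on a cloud already on the surface: unchanged
  ref <- cl$points[c(1, 5, 9), ]
  out0 <- align_eams(cl, b$mesh, ref, ref)
  expect_lt(max(sqrt(rowSums((out0$points - cl$points)^2))), 1e-6)
  # rotate 30 deg about z + translate 10 mm, exact pairs
  th <- 30 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- t(Rz %*% t(cl$points)) + matrix(c(10, 0, 0), nrow(cl$points), 3, byrow = TRUE)
  mref <- t(Rz %*% t(ref)) + matrix(c(10, 0, 0), 3, 3, byrow = TRUE)
  mcl <- eams_cloud(moved, cl$at, cl$region)
  back <- align_eams(mcl, b$mesh, mref, ref)
  rms <- sqrt(mean(rowSums((back$points - cl$points)^2)))
  expect_lt(rms, 0.5 * b$mesh$mean_edge)
  expect_identical(back$at, cl$at)
  # projection contract: every aligned point sits on a surface facet
  reproj <- crtsim:::project_to_surface(b$mesh, back$points)
  expect_lt(max(sqrt(rowSums((reproj - back$points)^2))), 1e-8)
  # collinear reference points are rejected
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(align_eams(cl, b$mesh, col, col), "collinear")
})
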