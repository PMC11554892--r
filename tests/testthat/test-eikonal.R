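# Anisotropic eikonal solver: tensor assembly, analytic front solutions,
# superposition, anisotropy, fibrosis monotonicity, LEAS.

test_that("conductivity tensor assembly matches direct substitution", {
  fb <- uniform_fibers(1, f = c(1, 0, 0), s = c(0, 1, 0))  # n = e3
  cp <- conductivity_params(sigma_f = 2.29e-4, sigma_s = 1.05e-4, sigma_n = 0.34e-4)
  D <- assemble_conductivity(fb, cp, 1)
  expect_equal(as.numeric(D), c(2.29e-4, 1.05e-4, 0.34e-4, 0, 0, 0))
  # isotropic degeneracy: D = z sigma I for any triad
  fb2 <- uniform_fibers(1, f = c(1, 2, 3), s = c(-1, 1, 0))
  Di <- assemble_conductivity(fb2, conductivity_params(1e-4, 1e-4, 1e-4), 0.5)
  expect_equal(as.numeric(Di), c(0.5e-4, 0.5e-4, 0.5e-4, 0, 0, 0))
  # z scales every entry linearly
  D7 <- assemble_conductivity(fb, cp, 0.7)
  expect_equal(as.numeric(D7), 0.7 * as.numeric(D))
  expect_error(conductivity_params(1e-4, 2e-4, 0.5e-4), "sigma")
})

test_that("homogeneous isotropic solution matches the analytic distance front", {
  bm <- build_box_mesh(20, 5, 5, h = 0.8)
  D <- assemble_conductivity(uniform_fibers(nrow(bm$elems)),
                             conductivity_params(1e-4, 1e-4, 1e-4), 1)
  psi <- solve_activation(bm, D, pacing_source(c(0, 0, 0), 0),
                          ep_params(c0 = 84.37), source_radius = 0)
  v <- 84.37 * sqrt(1e-4) * 1000          # mm/s
  truth <- sqrt(rowSums(bm$nodes^2)) / v
  far <- truth > 2 / v
  expect_lt(max(abs(psi$psi - truth)[far] / truth[far]), 0.02)
  # the 20 mm node arrives at distance/speed
  far_node <- which.min(rowSums((bm$nodes - matrix(c(20, 0, 0), nrow(bm$nodes), 3,
                                                   byrow = TRUE))^2))
  expect_equal(psi$psi[far_node], 0.020 / (84.37 * sqrt(1e-4)), tolerance = 0.01)
  # causality at the source
  src_node <- which.min(rowSums(bm$nodes^2))
  expect_equal(psi$psi[src_node], 0)
  expect_true(all(psi$psi >= 0))
})

test_that("convergence: error decreases under refinement at order >= 0.9", {
  errs <- vapply(c(1.6, 0.8), function(h) {
    bm <- build_box_mesh(16, 8, 8, h = h)
    D <- assemble_conductivity(uniform_fibers(nrow(bm$elems)),
                               conductivity_params(1e-4, 1e-4, 1e-4), 1)
    psi <- solve_activation(bm, D, pacing_source(c(0, 0, 0), 0),
                            ep_params(c0 = 80), source_radius = 0,
                            factor_radius = 3)
    truth <- sqrt(rowSums(bm$nodes^2)) / (80 * sqrt(1e-4) * 1000)
    max(abs(psi$psi - truth)[truth > 0])
  }, numeric(1))
  order <- log(errs[1] / errs[2]) / log(2)
  expect_gt(order, 0.9)
})

test_that("two equal-onset sources give the pointwise-min solution", {
  bm <- build_box_mesh(20, 5, 5, h = 1)
  D <- assemble_conductivity(uniform_fibers(nrow(bm$elems)),
                             conductivity_params(1e-4, 1e-4, 1e-4), 1)
  ep <- ep_params(c0 = 80)
  s1 <- pacing_source(c(0, 0, 0), 0)
  s2 <- pacing_source(c(20, 5, 5), 0)
  p1 <- solve_activation(bm, D, s1, ep)
  p2 <- solve_activation(bm, D, s2, ep)
  p12 <- solve_activation(bm, D, list(s1, s2), ep)
  expect_lt(max(abs(p12$psi - pmin(p1$psi, p2$psi))) /
              max(p12$psi), 0.01)
})

test_that("planar front speeds follow c0 sqrt(u' D u)", {
  # fibre direction speed for the reference anisotropic tensor
  bm <- build_box_mesh(20, 20, 4, h = 0.8)
  cp <- conductivity_params(sigma_f = 2.29e-4, sigma_s = 1.05e-4, sigma_n = 0.34e-4)
  D <- assemble_conductivity(uniform_fibers(nrow(bm$elems), f = c(1, 0, 0),
                                            s = c(0, 0, 1)), cp, 1)
  psi <- solve_activation(bm, D, pacing_source(c(0, 0, 0), 0),
                          ep_params(c0 = 84.37), source_radius = 0)
  node_f <- which.min(rowSums((bm$nodes - matrix(c(20, 0, 0), nrow(bm$nodes), 3,
                                                 byrow = TRUE))^2))
  node_n <- which.min(rowSums((bm$nodes - matrix(c(0, 20, 0), nrow(bm$nodes), 3,
                                                 byrow = TRUE))^2))
  v_f <- 0.020 / psi$psi[node_f]     # m/s
  expect_equal(v_f, 84.37 * sqrt(2.29e-4), tolerance = 0.02)  # ~1.277 m/s
  # anisotropy ratio along f vs n equals sqrt(sigma_f / sigma_n)
  expect_equal(psi$psi[node_n] / psi$psi[node_f], sqrt(2.29 / 0.34),
               tolerance = 0.02)
})

test_that("fibrosis never accelerates the front and z = 0 blocks conduction", {
  bm <- build_box_mesh(20, 5, 5, h = 1)
  fb <- uniform_fibers(nrow(bm$elems))
  cp <- conductivity_params()
  ep <- ep_params(c0 = 80)
  src <- pacing_source(c(0, 2.5, 2.5), 0)
  z1 <- rep(1, nrow(bm$elems))
  zmid <- ifelse(bm$elem_centroid[, 1] > 8 & bm$elem_centroid[, 1] < 12, 0.5, 1)
  p1 <- solve_activation(bm, assemble_conductivity(fb, cp, z1), src, ep)
  p2 <- solve_activation(bm, assemble_conductivity(fb, cp, zmid), src, ep)
  expect_true(all(p2$psi >= p1$psi - 1e-12))
  expect_gt(max(p2$psi), max(p1$psi))
  # a fully non-conducting slab leaves the far region unreached
  zblock <- ifelse(bm$elem_centroid[, 1] > 8 & bm$elem_centroid[, 1] < 12, 0, 1)
  expect_error(solve_activation(bm, assemble_conductivity(fb, cp, zblock), src, ep),
               "unreached")
})

test_that("curvature weight slows expanding fronts", {
  bm <- build_box_mesh(20, 20, 4, h = 1)
  D <- assemble_conductivity(uniform_fibers(nrow(bm$elems)),
                             conductivity_params(1e-4, 1e-4, 1e-4), 1)
  src <- pacing_source(c(0, 0, 0), 0)
  p0 <- solve_activation(bm, D, src, ep_params(c0 = 80, eps = 0))
  p1 <- solve_activation(bm, D, src, ep_params(c0 = 80, eps = 10),
                         curvature_maxit = 5)
  mid <- which.min(rowSums((bm$nodes - matrix(c(10, 10, 2), nrow(bm$nodes), 3,
                                              byrow = TRUE))^2))
  expect_gt(p1$psi[mid], p0$psi[mid])
})

test_that("LEAS is the latest vein-accessible position", {
  b <- test_bundle_clean()
  leas <- find_leas(b$psi_sinus, b$veins, b$mesh)
  acc <- b$veins$accessible
  at_all <- interp_activation(b$psi_sinus, b$mesh, as.matrix(acc[, c("x", "y", "z")]))
  expect_equal(leas$at, max(at_all))
  # LBBB truth (septal sources): LEAS falls in a lateral/anterolateral segment
  loc <- crtsim:::locate_points(b$mesh, as.numeric(leas[1, c("x", "y", "z")]))
  seg <- b$aha[loc$elem]
  expect_true(seg %in% c(5, 6, 11, 12, 16))
  # hand-set tie-break: maximum at the lowest (branch, arc) wins
  fake <- b$psi_sinus
  fake$psi[] <- 0
  l0 <- find_leas(fake, b$veins, b$mesh)
  expect_equal(l0$branch, 1)
  expect_equal(l0$arc, 0)
})
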