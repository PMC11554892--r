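# Reduced multipatch mechanics, phase machine, Windkessel and biomarkers.

test_that("passive stress law: reference state, fibrotic ratio, convexity", {
  up <- usyk_params()
  expect_equal(patch_passive_stress(1, up), 0)
  lam <- seq(1.02, 1.3, by = 0.02)
  s1 <- patch_passive_stress(lam, up, z = 1)
  s0 <- patch_passive_stress(lam, up, z = 0)
  expect_equal(s0 / s1, rep(4.56, length(lam)), tolerance = 1e-12)
  expect_true(all(diff(s1) > 0))
  expect_true(all(diff(diff(s1)) > 0))       # convex on [1, 1.3]
  expect_error(patch_passive_stress(-0.1), "positive")
})

test_that("single-patch passive equilibrium matches the Laplace sphere", {
  ps <- single_patch_set(v0 = 150, v_wall = 120)
  up <- usyk_params()
  # at the reference volume the wall is unloaded
  eq0 <- equilibrium_pressure(150, 0, ps, up)
  expect_equal(eq0$p, 0, tolerance = 1e-8)
  # inflated: p = 2 sigma h / r exactly (closed form)
  V <- 210
  r <- (3 * (V + 60) * 1000 / (4 * pi))^(1 / 3)
  lam <- r / ps$r_ref
  h <- ps$patches$v_w * 1000 / (4 * pi * r^2)
  p_exp <- kpa_to_mmhg(2 * patch_passive_stress(lam, up) * h / r)
  eq <- equilibrium_pressure(V, 0, ps, up)
  expect_equal(eq$p, p_exp, tolerance = 1e-6)
  expect_equal(eq$lambda, lam, tolerance = 1e-8)
})

test_that("N identical patches reproduce the single-patch solution", {
  up <- usyk_params()
  p1 <- equilibrium_pressure(200, 40, single_patch_set(), up)
  pN <- equilibrium_pressure(200, rep(40, 6), n_patch_set(6), up)
  expect_equal(pN$p, p1$p, tolerance = 1e-7)
  expect_equal(pN$lambda, rep(p1$lambda, 6), tolerance = 1e-7)
})

test_that("raising one patch tension raises cavity pressure", {
  up <- usyk_params()
  ps <- n_patch_set(4)
  base <- equilibrium_pressure(200, c(30, 30, 30, 30), ps, up)$p
  grid <- seq(35, 80, by = 15)
  ps_vals <- vapply(grid, function(ta1)
    equilibrium_pressure(200, c(ta1, 30, 30, 30), ps, up)$p, numeric(1))
  expect_true(all(diff(c(base, ps_vals)) > 0))
})

test_that("end-diastolic pressure determination hits the target volume", {
  ps <- test_mechcal(test_bundle_clean())$patches
  up <- usyk_params()
  edp <- find_edp(350, ps, up)
  expect_lt(abs(edp$v - 350), 0.5)
  # monotone: a larger EDV needs a larger filling pressure
  edp2 <- find_edp(380, ps, up)
  expect_gt(edp2$p_ed, edp$p_ed)
  # globally fibrotic wall is stiffer: higher pressure for the same volume
  ps_fib <- ps; ps_fib$patches$z <- 0
  edp_fib <- find_edp(350, ps_fib, up)
  expect_gt(edp_fib$p_ed, edp$p_ed)
  expect_error(find_edp(ps$v0 - 20, ps, up), "infeasible")
})

test_that("a beat runs through the four phases with isovolumic fidelity", {
  b <- test_bundle_clean()
  mc <- test_mechcal(b)
  ps <- mc$patches
  ps$patches$t_act[] <- 0.02            # near-synchronous activation
  ca <- calcium_transient(b$record$hr, dt = 2.5e-4)
  atp <- active_tension_params(a_xb = mc$a_xb)
  traces <- lapply(seq_len(nrow(ps$patches)), function(i)
    active_tension(ca, atp, z = 1, t_act = ps$patches$t_act[i]))
  wk <- windkessel_params(R = mc$R, p_mvo = min(5, 0.6 * mc$p_ed),
                          p_ed = mc$p_ed, p_d = b$record$p_d)
  loop <- run_beat(b$record$edv, ps, traces, usyk_params(), wk, b$record$hr,
                   dt = 2.5e-4)
  phases <- rle(loop$phase)$values
  expect_equal(phases, c("isovolumic-contraction", "ejection",
                         "isovolumic-relaxation", "filling"))
  for (ph in c("isovolumic-contraction", "isovolumic-relaxation")) {
    vs <- loop$v[loop$phase == ph]
    expect_lt(max(abs(vs - vs[1])), 0.1)
  }
  bm <- compute_biomarkers(loop)
  expect_gt(bm$sv, 0)
  # dyssynchrony penalty: delaying the lateral wall 80 ms lowers dP/dt_max and SV
  ps_dys <- ps
  ps_dys$patches$t_act[ps_dys$patches$id %in% c(5, 6, 11, 12, 16)] <- 0.10
  traces_d <- lapply(seq_len(nrow(ps$patches)), function(i)
    active_tension(ca, atp, z = 1, t_act = ps_dys$patches$t_act[i]))
  loop_d <- run_beat(b$record$edv, ps_dys, traces_d, usyk_params(), wk,
                     b$record$hr, dt = 2.5e-4)
  bm_d <- compute_biomarkers(loop_d)
  expect_lt(bm_d$dpdt_max, bm$dpdt_max)
  expect_lt(bm_d$sv, bm$sv)
})

test_that("chained beats settle on a limit cycle and are deterministic", {
  b <- test_bundle_clean()
  mc <- test_mechcal(b)
  ps <- mc$patches
  ca <- calcium_transient(b$record$hr, dt = 2.5e-4)
  atp <- active_tension_params(a_xb = mc$a_xb)
  traces <- lapply(seq_len(nrow(ps$patches)), function(i)
    active_tension(ca, atp, z = ps$patches$z[i], t_act = ps$patches$t_act[i]))
  wk <- windkessel_params(R = mc$R, p_mvo = min(5, 0.6 * mc$p_ed),
                          p_ed = mc$p_ed, p_d = b$record$p_d)
  lc <- run_to_limit_cycle(b$record$edv, ps, traces, usyk_params(), wk,
                           b$record$hr, dt = 2.5e-4, n_beats = 4L)
  s <- lc$summary
  expect_lt(abs(s$sv[4] - s$sv[3]) / s$sv[4], 0.01)
  lc1 <- run_to_limit_cycle(b$record$edv, ps, traces, usyk_params(), wk,
                            b$record$hr, dt = 2.5e-4, n_beats = 1L)
  expect_equal(nrow(lc1$summary), 1)
  lc2 <- run_to_limit_cycle(b$record$edv, ps, traces, usyk_params(), wk,
                            b$record$hr, dt = 2.5e-4, n_beats = 4L)
  expect_identical(lc$loop, lc2$loop)
})

test_that("biomarkers follow their defining arithmetic", {
  # EF from printed clinical volumes
  mk_loop <- function(p, v) {
    structure(data.frame(t = seq_along(p) * 1e-4, p = p, v = v,
                         phase = "ejection"), class = c("pv_loop", "data.frame"))
  }
  bm <- compute_biomarkers(mk_loop(c(10, 60, 110), c(501, 460, 425)))
  expect_equal(bm$ef, 100 * 76 / 501, tolerance = 1e-12)   # 15.2% for P2
  # rectangular loop: SW = dp * dV = 10 mmHg * 50 ml
  rect <- mk_loop(c(0, 0, 10, 10), c(100, 150, 150, 100))
  expect_equal(compute_biomarkers(rect)$sw, 500, tolerance = 1e-9)
  # constant pressure: dP/dt_max = 0
  flat <- mk_loop(c(5, 5, 5), c(120, 110, 100))
  expect_equal(compute_biomarkers(flat)$dpdt_max, 0)
  expect_error(compute_biomarkers(mk_loop(5, 100)), "3 samples")
})

test_that("stroke work agrees with the independent power-integral oracle", {
  b <- test_bundle_clean()
  mc <- test_mechcal(b)
  ps <- mc$patches
  ca <- calcium_transient(b$record$hr, dt = 2.5e-4)
  traces <- lapply(seq_len(nrow(ps$patches)), function(i)
    active_tension(ca, active_tension_params(a_xb = mc$a_xb),
                   z = ps$patches$z[i], t_act = ps$patches$t_act[i]))
  wk <- windkessel_params(R = mc$R, p_mvo = min(5, 0.6 * mc$p_ed),
                          p_ed = mc$p_ed, p_d = b$record$p_d)
  loop <- run_beat(b$record$edv, ps, traces, usyk_params(), wk, b$record$hr,
                   dt = 2.5e-4)
  sw <- compute_biomarkers(loop)$sw
  # independent oracle: integral of p * (-dV/dt) dt over the beat
  dv <- diff(loop$v); pm <- (loop$p[-1] + loop$p[-nrow(loop)]) / 2
  sw_oracle <- -sum(pm * dv) - (loop$p[1] + loop$p[nrow(loop)]) / 2 *
    (loop$v[1] - loop$v[nrow(loop)])
  expect_lt(abs(sw - sw_oracle) / sw, 0.005)
})

test_that("calibration-relevant responses are monotone", {
  b <- test_bundle_clean()
  mc <- test_mechcal(b)
  run1 <- function(a_xb, R) {
    ps <- mc$patches
    ca <- calcium_transient(b$record$hr, dt = 5e-4)
    traces <- lapply(seq_len(nrow(ps$patches)), function(i)
      active_tension(ca, active_tension_params(a_xb = a_xb),
                     z = ps$patches$z[i], t_act = ps$patches$t_act[i]))
    wk <- windkessel_params(R = R, p_mvo = min(5, 0.6 * mc$p_ed),
                            p_ed = mc$p_ed, p_d = b$record$p_d)
    compute_biomarkers(run_beat(b$record$edv, ps, traces, usyk_params(), wk,
                                b$record$hr, dt = 5e-4))
  }
  esv <- vapply(c(0.06, 0.08, 0.1), function(a) run1(a, 0.2)$esv, numeric(1))
  expect_true(all(diff(esv) < 0))           # ESV strictly decreasing in a_XB
  pmax_ <- vapply(c(0.15, 0.2, 0.26), function(R) run1(0.08, R)$p_max, numeric(1))
  expect_true(all(diff(pmax_) > 0))         # P_S strictly increasing in R
})
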