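# Shared fixtures, built once per test session and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small LV mesh for geometry tests (coarse but full-featured)
test_mesh <- function() fixture("mesh", function() build_lv_mesh(target_h = 5))

# Default synthetic patient bundle (noisy EAMS, study conditions)
test_bundle <- function() {
  fixture("bundle", function() suppressWarnings(synth_patient_bundle(seed = 7)))
}

# Noise-free twin of the same bundle (shares geometry/truth parameters)
test_bundle_clean <- function() {
  fixture("bundle_clean", function() {
    suppressWarnings(synth_patient_bundle(seed = 7, noise_sd = 0))
  })
}

# A stand-in personalized parameter pair used where the tests exercise the
# scenario engine without paying for a full mechanical calibration.
test_epcal <- function(bundle) {
  structure(list(c0 = bundle$ep_truth$c0, eps = bundle$ep_truth$eps,
                 z = bundle$ep_truth$z_fibrotic, e = 0, converged = TRUE),
            class = "ep_calibration")
}

test_mechcal <- function(bundle, a_xb = 0.08, R = 0.2, dt = 2.5e-4, n_beats = 2L) {
  ps <- make_patches(bundle$mesh, bundle$aha, bundle$fibrosis, bundle$psi_sinus)
  edp <- find_edp(bundle$record$edv, ps)
  structure(list(a_xb = a_xb, R = R, p_ed = edp$p_ed, converged = TRUE,
                 dt = dt, n_beats = n_beats, patches = ps),
            class = "mech_calibration")
}

# One-patch set with prescribed geometry for closed-form mechanics checks.
single_patch_set <- function(v0 = 150, v_wall = 120) {
  r_ref <- (3 * (v0 + v_wall / 2) * 1000 / (4 * pi))^(1 / 3)
  structure(list(
    patches = data.frame(id = 1L, v_w = v_wall, phi = 1, z = 1, t_act = 0),
    v0 = v0, v_wall = v_wall, r_ref = r_ref,
    a_ref = 4 * pi * r_ref^2
  ), class = "patch_set")
}

n_patch_set <- function(n, v0 = 150, v_wall = 120, z = rep(1, n),
                        t_act = rep(0, n)) {
  r_ref <- (3 * (v0 + v_wall / 2) * 1000 / (4 * pi))^(1 / 3)
  structure(list(
    patches = data.frame(id = seq_len(n), v_w = v_wall / n, phi = 1 / n,
                         z = z, t_act = t_act),
    v0 = v0, v_wall = v_wall, r_ref = r_ref,
    a_ref = rep(4 * pi * r_ref^2 / n, n)
  ), class = "patch_set")
}

# Cached calibrations (shared between the unit and acceptance suites)
test_epcal_clean <- function() {
  fixture("epcal_clean", function() {
    calibrate_ep(test_bundle_clean(), eps_grid = c(0, 10), sweeps = 1L)
  })
}

test_epcal_noisy <- function() {
  fixture("epcal_noisy", function() calibrate_ep(test_bundle()))
}

# Inverse-crime mechanical recovery (expensive; shared by unit + acceptance)
test_mech_recovery <- function() {
  fixture("mech_recovery", function() {
    b <- test_bundle_clean()
    mc_ref <- test_mechcal(b, a_xb = 0.08, R = 0.2)
    ps <- mc_ref$patches
    ca <- calcium_transient(b$record$hr, dt = 2.5e-4)
    traces <- lapply(seq_len(nrow(ps$patches)), function(i)
      active_tension(ca, active_tension_params(a_xb = 0.08),
                     z = ps$patches$z[i], t_act = ps$patches$t_act[i]))
    wk <- windkessel_params(R = 0.2, p_mvo = min(5, 0.6 * mc_ref$p_ed),
                            p_ed = mc_ref$p_ed, p_d = b$record$p_d)
    bm <- compute_biomarkers(run_to_limit_cycle(b$record$edv, ps, traces,
                                                usyk_params(), wk, b$record$hr,
                                                dt = 2.5e-4, n_beats = 3L)$loop)
    rec <- b$record
    rec$esv <- bm$esv; rec$p_s <- bm$p_max
    rec$sv <- rec$edv - rec$esv; rec$ef <- 100 * rec$sv / rec$edv
    list(mc = calibrate_mech(b, b$psi_sinus, record = rec, a_xb0 = 0.06,
                             R0 = 0.3, dt = 2.5e-4, n_beats = 3L),
         a_true = 0.08, r_true = 0.2)
  })
}
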