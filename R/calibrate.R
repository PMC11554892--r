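# Two-stage personalization: electrical calibration against coronary-sinus
# mapping times (coordinate descent over c0, then the curvature weight, then
# the fibrosis factor), right-pacing cross-validation, and mechanical
# calibration of contractility and afterload against ESV and systolic
# pressure.

#' Relative activation-time calibration error
#'
#' `e[%] = 100 * sum(|t_clin - t_comp|) / (N * T_max)` where `N` is the number
#' of clinically recorded times and `T_max` the maximum clinically recorded
#' time of the comparison at hand.
#'
#' @param t_clin clinically recorded activation times (s).
#' @param t_comp computed activation times at the same points (s).
#' @return The error in percent.
#' @export
calibration_error <- function(t_clin, t_comp) {
  if (length(t_clin) != length(t_comp)) stop("time vectors must have equal length")
  if (length(t_clin) < 1) stop("need at least one recorded time")
  t_max <- max(t_clin)
  if (t_max <= 0) stop("maximum recorded activation time must be positive")
  100 * sum(abs(t_clin - t_comp)) / (length(t_clin) * t_max)
}

# Simulate the sinus protocol at given EP parameters and evaluate the error on
# a cloud. Sources: measured septal times when available, else the bundle's
# fixed surrogate points.
.ep_error <- function(bundle, cloud, c0, eps, z) {
  cp <- bundle$conductivity
  D <- assemble_conductivity(bundle$fibers, cp, .z_field(bundle, z))
  psi <- solve_activation(bundle$mesh, D, bundle$sinus_sources,
                          ep_params(c0 = c0, eps = eps,
                                    z_fibrotic = max(z, 1e-3)),
                          curvature_maxit = 3L)
  t_comp <- interp_activation(psi, bundle$mesh, cloud$points)
  calibration_error(cloud$at, t_comp)
}

# Per-element z field with the fibrotic factor replaced by a candidate value.
.z_field <- function(bundle, z_value) {
  z <- bundle$fibrosis$z
  z[z < 1] <- z_value
  if (all(z == 1) && z_value < 1) z else z   # healthy bundles ignore z_value
}

.golden <- function(f, lo, hi, tol, trace = NULL) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while ((b - a) > tol) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- f(x1) }
    else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- f(x2) }
  }
  if (f1 <= f2) list(x = x1, f = f1) else list(x = x2, f = f2)
}

#' Electrical calibration by coordinate descent
#'
#' Personalizes the eikonal parameters against the coronary-sinus activation
#' times of a mapped cloud, in the stated order: (1) golden-section
#' minimization of the error over the planar-front rate `c0`; (2) grid +
#' golden-section refinement of the curvature weight `eps`; (3) for fibrotic
#' bundles, a grid over the fibrosis factor `z` in {0.5, ..., 1.0}. At most
#' two outer sweeps; converged iff the final error is below 10%.
#'
#' @param bundle a `patient_bundle`.
#' @param cloud the coronary-sinus `eams_cloud` used for calibration (default:
#'   the bundle's sinus cloud restricted to the "cs" region).
#' @param c0_range search bracket for c0 (s^(-1/2)).
#' @param c0_tol golden-section tolerance on c0.
#' @param eps_grid curvature-weight candidate grid.
#' @param z_grid fibrosis-factor candidate grid (fibrotic bundles only).
#' @param sweeps maximum outer coordinate-descent sweeps.
#' @return An object of class `ep_calibration`: `c0`, `eps`, `z`, final error
#'   `e` (%), `converged`, and the accepted-step `trace`.
#' @export
calibrate_ep <- function(bundle, cloud = NULL, c0_range = c(40, 140),
                         c0_tol = 0.5, eps_grid = c(0, 5, 10, 20),
                         z_grid = seq(0.5, 1.0, by = 0.1), sweeps = 2L) {
  if (is.null(cloud)) {
    sel <- bundle$eams_sinus$region == "cs"
    cloud <- eams_cloud(bundle$eams_sinus$points[sel, , drop = FALSE],
                        bundle$eams_sinus$at[sel],
                        bundle$eams_sinus$region[sel])
  }
  fibrotic <- any(bundle$fibrosis$z < 1)
  c0 <- mean(c0_range); eps <- 0; z <- 1
  trace <- data.frame(step = character(0), c0 = numeric(0), eps = numeric(0),
                      z = numeric(0), e = numeric(0))
  push <- function(step, e) {
    trace[nrow(trace) + 1L, ] <<- list(step, c0, eps, z, e)
  }

  e_cur <- .ep_error(bundle, cloud, c0, eps, z)
  push("init", e_cur)
  for (sw in seq_len(sweeps)) {
    # (1) conduction rate
    opt <- .golden(function(x) .ep_error(bundle, cloud, x, eps, z),
                   c0_range[1], c0_range[2], c0_tol)
    if (opt$f <= e_cur) { c0 <- opt$x; e_cur <- opt$f }
    push("c0", e_cur)
    # (2) curvature weight: coarse grid, then refine around the best cell
    eg <- vapply(eps_grid, function(x) .ep_error(bundle, cloud, c0, x, z), numeric(1))
    bi <- which.min(eg)
    improves <- eg[bi] < e_cur - 0.1
    if (eg[bi] <= e_cur) { eps <- eps_grid[bi]; e_cur <- eg[bi] }
    lo <- eps_grid[max(1, bi - 1)]; hi <- eps_grid[min(length(eps_grid), bi + 1)]
    # golden refinement only where the grid shows a real curvature benefit
    if (hi > lo && improves) {
      opt <- .golden(function(x) .ep_error(bundle, cloud, c0, x, z), lo, hi, 1.0)
      if (opt$f <= e_cur) { eps <- opt$x; e_cur <- opt$f }
    }
    push("eps", e_cur)
    # (3) fibrosis factor
    if (fibrotic) {
      zg <- vapply(z_grid, function(x) .ep_error(bundle, cloud, c0, eps, x), numeric(1))
      bi <- which.min(zg)
      if (zg[bi] <= e_cur) { z <- z_grid[bi]; e_cur <- zg[bi] }
      push("z", e_cur)
    }
    if (e_cur < 10 && sw >= 1) break
  }
  structure(list(c0 = c0, eps = eps, z = z, e = e_cur,
                 converged = e_cur < 10, trace = trace),
            class = "ep_calibration")
}

#' @export
print.ep_calibration <- function(x, ...) {
  cat(sprintf("EP calibration: c0 = %.2f s^-1/2, eps = %.2f, z = %.2f; e = %.2f%% (%s)\n",
              x$c0, x$eps, x$z, x$e,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Right-pacing cross-validation of an electrical calibration
#'
#' Simulates the right-pacing protocol with the calibrated parameters and
#' reports: the validation error (right-pacing cloud vs right-pacing
#' simulation), `e_I` (right-pacing cloud vs the *sinus* simulation at those
#' points) and `e_II` (sinus cloud vs the *right-pacing* simulation at those
#' points). Large `e_I`/`e_II` relative to the validation error certify that
#' the two protocols carry genuinely different information.
#'
#' @param bundle a `patient_bundle`.
#' @param cal an `ep_calibration`.
#' @param sinus_cloud,rp_cloud mapped clouds (defaults: the bundle's cs-region
#'   sinus cloud and its right-pacing cloud).
#' @return An object of class `ep_validation` with `validation`, `e_I`, `e_II`
#'   (percent).
#' @export
cross_validate <- function(bundle, cal, sinus_cloud = NULL, rp_cloud = NULL) {
  if (is.null(sinus_cloud)) {
    sel <- bundle$eams_sinus$region == "cs"
    sinus_cloud <- eams_cloud(bundle$eams_sinus$points[sel, , drop = FALSE],
                              bundle$eams_sinus$at[sel],
                              bundle$eams_sinus$region[sel])
  }
  if (is.null(rp_cloud)) rp_cloud <- bundle$eams_rp
  if (nrow(rp_cloud$points) < 1 || nrow(sinus_cloud$points) < 1)
    stop("validation clouds must be non-empty")

  D <- assemble_conductivity(bundle$fibers, bundle$conductivity,
                             .z_field(bundle, cal$z))
  epp <- ep_params(c0 = cal$c0, eps = cal$eps, z_fibrotic = max(cal$z, 1e-3))
  psi_sin <- solve_activation(bundle$mesh, D, bundle$sinus_sources, epp,
                              curvature_maxit = 8L)
  psi_rp <- solve_activation(bundle$mesh, D, bundle$rp_sources, epp,
                             curvature_maxit = 8L)

  at_rp_sim_rp <- interp_activation(psi_rp, bundle$mesh, rp_cloud$points)
  at_rp_sim_sin <- interp_activation(psi_sin, bundle$mesh, rp_cloud$points)
  at_sin_sim_rp <- interp_activation(psi_rp, bundle$mesh, sinus_cloud$points)

  structure(list(
    validation = calibration_error(rp_cloud$at, at_rp_sim_rp),
    e_I = calibration_error(rp_cloud$at, at_rp_sim_sin),
    e_II = calibration_error(sinus_cloud$at, at_sin_sim_rp),
    psi_sinus = psi_sin, psi_rp = psi_rp
  ), class = "ep_validation")
}

#' @export
print.ep_validation <- function(x, ...) {
  cat(sprintf("Validation error %.1f%%; e_I %.1f%%, e_II %.1f%%\n",
              x$validation, x$e_I, x$e_II))
  invisible(x)
}

#' Mechanical calibration of contractility and afterload
#'
#' With the electrical calibration fixed and the preload determined
#' (`p_ed = find_edp(EDV)`), fits the contractility `a_XB` and the Windkessel
#' resistance `R` to the two remaining clinical targets, ESV and systolic
#' pressure `P_S`, via a local-linear surrogate: a small full-model design
#' estimates the 2x2 response Jacobian, Newton-style steps on the surrogate
#' are verified with full limit-cycle runs, and the Jacobian is refreshed by
#' Broyden updates. Success iff |dESV| <= 1 ml and |dP_S| <= 1 mmHg.
#'
#' @param bundle a `patient_bundle` (or anything carrying mesh/aha/fibrosis).
#' @param psi calibrated sinus `activation_map` driving patch activation.
#' @param record patient record (targets ESV, P_S; inputs EDV, P_D, HR).
#' @param a_xb0,R0 initial guesses.
#' @param bounds list with `a_xb` and `R` (each c(lo, hi)).
#' @param dt,n_beats mechanics settings for the calibration runs.
#' @param max_iter Newton iteration cap.
#' @return An object of class `mech_calibration`: `a_xb`, `R`, `p_ed`,
#'   residuals, `converged`, and the fitted model state.
#' @export
calibrate_mech <- function(bundle, psi, record = bundle$record,
                           a_xb0 = 0.08, R0 = 0.2,
                           bounds = list(a_xb = c(0.02, 3), R = c(0.02, 5)),
                           dt = 2.5e-4, n_beats = 3L, max_iter = 8L) {
  ps <- make_patches(bundle$mesh, bundle$aha, bundle$fibrosis, psi)
  up <- usyk_params()
  edp <- find_edp(record$edv, ps, up)
  hr <- record$hr
  ca <- calcium_transient(hr, dt = dt)

  run_at <- function(a_xb, R) {
    atp <- active_tension_params(a_xb = a_xb)
    traces <- lapply(seq_len(nrow(ps$patches)), function(i) {
      active_tension(ca, atp, z = ps$patches$z[i], t_act = ps$patches$t_act[i])
    })
    wk <- windkessel_params(R = R, p_mvo = min(5, 0.6 * edp$p_ed),
                            p_ed = edp$p_ed, p_d = record$p_d)
    lc <- run_to_limit_cycle(record$edv, ps, traces, up, wk, hr, dt, n_beats)
    bm <- compute_biomarkers(lc$loop)
    c(esv = bm$esv, p_s = bm$p_max)
  }

  target <- c(record$esv, record$p_s)
  x <- c(a_xb0, R0)
  y <- run_at(x[1], x[2])
  # initial Jacobian from a 2-run design (one perturbation per parameter)
  d1 <- 0.15 * x[1]; d2 <- 0.15 * x[2]
  y1 <- run_at(x[1] + d1, x[2])
  y2 <- run_at(x[1], x[2] + d2)
  J <- cbind((y1 - y) / d1, (y2 - y) / d2)

  hist <- data.frame(iter = 0L, a_xb = x[1], R = x[2],
                     esv = y[1], p_s = y[2])
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    res <- y - target
    # iterate beyond the success tolerance (1 ml / 1 mmHg): the parameter
    # slack the residual box leaves is larger than the recovery accuracy the
    # fit is expected to deliver
    if (abs(res[1]) <= 0.25 && abs(res[2]) <= 0.25) { converged <- TRUE; break }
    step <- tryCatch(as.numeric(-solve(J, res)), error = function(e) c(0, 0))
    # damp and box-constrain
    xn <- x + pmin(pmax(step, -0.6 * x), 0.6 * x)
    xn[1] <- min(max(xn[1], bounds$a_xb[1]), bounds$a_xb[2])
    xn[2] <- min(max(xn[2], bounds$R[1]), bounds$R[2])
    yn <- run_at(xn[1], xn[2])
    s <- xn - x; dy <- yn - y
    if (sum(s^2) > 0) J <- J + (dy - as.numeric(J %*% s)) %o% s / sum(s^2)
    x <- xn; y <- yn
    hist <- rbind(hist, data.frame(iter = it, a_xb = x[1], R = x[2],
                                   esv = y[1], p_s = y[2]))
  }
  res <- y - target
  converged <- abs(res[1]) <= 1 && abs(res[2]) <= 1
  if (!converged &&
      (any(abs(x[1] - bounds$a_xb) < 1e-9) || any(abs(x[2] - bounds$R) < 1e-9)))
    warning("mechanical calibration hit a parameter bound")
  structure(list(a_xb = x[1], R = x[2], p_ed = edp$p_ed,
                 residual_esv = res[1], residual_ps = res[2],
                 converged = converged, trace = hist,
                 patches = ps, dt = dt, n_beats = n_beats),
            class = "mech_calibration")
}

#' @export
print.mech_calibration <- function(x, ...) {
  cat(sprintf("Mechanical calibration: a_XB = %.3f MPa, R = %.3f mmHg s/ml, p_ED = %.2f mmHg\n",
              x$a_xb, x$R, x$p_ed))
  cat(sprintf("  residuals: ESV %+.2f ml, P_S %+.2f mmHg (%s)\n",
              x$residual_esv, x$residual_ps,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
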