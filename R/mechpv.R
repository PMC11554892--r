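# Reduced multipatch LV mechanics coupled to the cardiac-cycle phase machine:
# linear-ramp filling, isovolumic phases with the cavity pressure acting as a
# Lagrange multiplier on the volume constraint, and a two-element Windkessel
# during ejection.
#
# The 3D continuum is reduced to N thick-membrane patches on a spherical
# midwall shell: patch areas redistribute under a common wall tension
# (Laplace balance p = 2 T / r), which preserves the couplings the scenario
# engine needs - activation-shifted active tension, fibrosis scalings of
# stiffness and contractility, the phase machine and the Windkessel afterload.

#' Usyk-type passive material constants
#' @param b_f,b_s,b_n,b_fs,b_fn,b_sn exponent weights (dimensionless).
#' @param c_usyk stress scale (kPa).
#' @param k_pen incompressibility penalty (kPa); carried but unused in the
#'   membrane reduction.
#' @return An object of class `usyk_params`.
#' @export
usyk_params <- function(b_f = 8, b_s = 6, b_n = 3, b_fs = 12, b_fn = 3,
                        b_sn = 3, c_usyk = 0.88, k_pen = 50) {
  stopifnot(b_f > 0, b_s > 0, b_n > 0, c_usyk > 0)
  structure(list(b_f = b_f, b_s = b_s, b_n = b_n, b_fs = b_fs, b_fn = b_fn,
                 b_sn = b_sn, c_usyk = c_usyk, k_pen = k_pen),
            class = "usyk_params")
}

#' Two-element Windkessel / preload parameters
#' @param R arterial resistance (mmHg s/ml).
#' @param C compliance (ml/mmHg); default converts the reference
#'   4.5e-9 m^3/Pa.
#' @param p_mvo mitral valve opening pressure (mmHg).
#' @param p_ed end-diastolic pressure (mmHg); per patient from [find_edp()].
#' @param p_d aortic opening (diastolic arterial) pressure (mmHg).
#' @return An object of class `windkessel_params`.
#' @export
windkessel_params <- function(R = 0.25, C = 0.6, p_mvo = 5, p_ed = 10, p_d = 75) {
  stopifnot(R > 0, C > 0)
  if (p_mvo >= p_ed) stop("require p_mvo < p_ed")
  structure(list(R = R, C = C, p_mvo = p_mvo, p_ed = p_ed, p_d = p_d),
            class = "windkessel_params")
}

#' Uniaxial fibre-direction passive Cauchy stress with fibrotic stiffening
#'
#' Derived from the exponential strain energy `W = C/2 (exp(Q) - 1)` with
#' `Q = b_f E_ff^2 + b_s E_ss^2 + b_n E_nn^2` under isochoric uniaxial-fibre
#' kinematics `E_ff = (lambda^2 - 1)/2`, `E_ss = E_nn = (1/lambda - 1)/2`
#' (shear terms vanish in this mode). The result is multiplied by the fibrotic
#' stiffening factor `s(z) = z + (1 - z) * 4.56`.
#'
#' @param lambda fibre stretch (> 0), vectorized.
#' @param up a `usyk_params`.
#' @param z fibrosis scalar in `[0, 1]` (1 healthy).
#' @return Cauchy stress (kPa).
#' @export
patch_passive_stress <- function(lambda, up = usyk_params(), z = 1) {
  if (any(lambda <= 0)) stop("fibre stretch must be positive")
  e_f <- (lambda^2 - 1) / 2
  e_t <- (1 / lambda - 1) / 2
  q <- up$b_f * e_f^2 + (up$b_s + up$b_n) * e_t^2
  dq <- 2 * up$b_f * e_f * lambda - (up$b_s + up$b_n) * e_t / lambda^2
  sigma <- lambda * (up$c_usyk / 2) * exp(q) * dq
  (z + (1 - z) * 4.56) * sigma
}

#' Build mechanical patches from a bundle's mesh fields
#'
#' One patch per AHA segment: wall volume, reference midwall area fraction,
#' volume-weighted mean fibrosis and (when an activation map is given)
#' volume-weighted mean activation time.
#'
#' @param mesh an `lv_mesh`.
#' @param aha per-element AHA segment ids.
#' @param z per-element fibrosis (or `fibrosis_field`).
#' @param psi optional `activation_map` giving patch activation times.
#' @return An object of class `patch_set`: data.frame of patches plus the
#'   reference cavity volume `v0` (ml), total wall volume (ml) and reference
#'   midwall radius (mm).
#' @export
make_patches <- function(mesh, aha, z = 1, psi = NULL) {
  if (inherits(z, "fibrosis_field")) z <- z$z
  z <- rep_len(z, nrow(mesh$elems))
  vol <- mesh$elem_volume
  t_elem <- if (is.null(psi)) rep(0, nrow(mesh$elems)) else
    rowMeans(matrix(psi$psi[mesh$elems], ncol = 8))
  segs <- sort(unique(aha))
  vw <- vapply(segs, function(s) sum(vol[aha == s]), numeric(1))
  zi <- vapply(segs, function(s) sum((z * vol)[aha == s]) / sum(vol[aha == s]), numeric(1))
  ti <- vapply(segs, function(s) sum((t_elem * vol)[aha == s]) / sum(vol[aha == s]), numeric(1))
  v0 <- cavity_volume(mesh) / 1000              # ml
  vw_ml <- vw / 1000
  r_ref <- (3 * (v0 + sum(vw_ml) / 2) * 1000 / (4 * pi))^(1 / 3)   # mm
  phi <- vw / sum(vw)
  structure(list(
    patches = data.frame(id = segs, v_w = vw_ml, phi = phi, z = zi, t_act = ti),
    v0 = v0, v_wall = sum(vw_ml), r_ref = r_ref,
    a_ref = phi * 4 * pi * r_ref^2               # mm^2
  ), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("Patch set: %d patches, cavity %.1f ml, wall %.1f ml, r_ref %.1f mm\n",
              nrow(x$patches), x$v0, x$v_wall, x$r_ref))
  invisible(x)
}

# Geometry helpers shared by the static balance and the dynamic stepper.
.shell_radius <- function(V_ml, v_wall) (3 * (V_ml + v_wall / 2) * 1000 / (4 * pi))^(1 / 3)

# Per-patch fibrotic-stiffened passive Cauchy stress.
.sig_pass <- function(l, up, z) patch_passive_stress(l, up, z = 1) * (z + (1 - z) * 4.56)

# Static tension/pressure balance. state: list(lambda (N), tension (kPa mm)).
# ta_i: active tension per patch (kPa), entering as a fibre-direction second
# Piola-Kirchhoff stress (Cauchy = lambda^2 ta, J = 1). Patch tension is
# strictly increasing in stretch, so the stretches are inverted per patch by
# bracketed Newton and the common tension found by bisection on the area
# constraint. Returns p (mmHg) and the state.
.equilibrium <- function(V_ml, ta_i, ps, up, state = NULL, tol = 1e-10,
                         maxit = 70L) {
  pt <- ps$patches
  N <- nrow(pt)
  r <- .shell_radius(V_ml, ps$v_wall)
  S <- 4 * pi * r^2
  a_ref <- ps$a_ref
  v_w <- pt$v_w * 1000                                           # mm^3

  lam <- if (is.null(state)) rep(sqrt(S / sum(a_ref)), N) else state$lambda
  lam <- pmin(pmax(lam, 0.4), 2.5)

  t_of <- function(l) (.sig_pass(l, up, pt$z) + ta_i * l^2) * v_w / (a_ref * l^2)
  dt_dl <- function(l, h = 1e-7) (t_of(l * (1 + h)) - t_of(l * (1 - h))) / (2 * l * h)

  lam_of_T <- function(Tt, l0) {
    lo <- rep(0.4, N); hi <- rep(2.5, N)
    l <- pmin(pmax(l0, 0.4 + 1e-9), 2.5 - 1e-9)
    fscale <- max(1, abs(Tt))
    for (it in 1:60) {
      f <- t_of(l) - Tt
      if (all(abs(f) <= 1e-11 * fscale | (hi - lo) < 1e-14)) break
      neg <- f < 0
      lo[neg] <- l[neg]; hi[!neg] <- l[!neg]
      d <- dt_dl(l)
      d[!is.finite(d) | d < 1e-12] <- 1e-12
      ln <- l - f / d
      mid <- (lo + hi) / 2
      out <- !(ln > lo & ln < hi)
      ln[out] <- mid[out]
      l <- ln
    }
    l
  }

  # the solution tension lies between the patch tensions at the
  # area-equalizing stretch (some patch must sit above it, some below)
  lam_eq <- sqrt(S / sum(a_ref))
  t_eq <- t_of(rep(lam_eq, N))
  T_lo <- min(t_eq); T_hi <- max(t_eq)
  if (T_hi - T_lo < 1e-12) {
    Tn <- T_lo
    lam <- rep(lam_eq, N)
  } else {
    l_warm <- lam
    g_of <- function(Tt) {
      l_warm <<- lam_of_T(Tt, l_warm)
      sum(a_ref * l_warm^2) - S
    }
    Ta <- T_lo; Tb <- T_hi
    Tn <- (Ta + Tb) / 2
    for (it in seq_len(maxit)) {
      Tn <- (Ta + Tb) / 2
      gc <- g_of(Tn)
      if (abs(gc) / S < tol || (Tb - Ta) < 1e-13 * max(1, abs(Tb))) break
      if (gc < 0) Ta <- Tn else Tb <- Tn
    }
    lam <- l_warm
  }
  G <- sum(a_ref * lam^2) - S
  if (abs(G) / S > 1e-6)
    stop(sprintf("patch equilibrium failed to converge (V %.1f ml)", V_ml))
  p_kpa <- 2 * Tn / r
  list(p = kpa_to_mmhg(p_kpa), lambda = lam, tension = Tn, r = r)
}

# One explicit viscous time step of the multipatch shell. Patch stretches are
# dynamic states with Kelvin-Voigt dynamics
#   eta_i h_i dlambda_i/dt = T - T_i(lambda_i),
# eta_i = eta0 + k_fv * ta_i (activation-proportional Hill force-velocity plus
# a small tissue baseline). With lambda advanced explicitly the area
# constraint Sum a_ref lambda^2 = 4 pi r(V)^2 is a scalar quadratic in the
# common tension T: closed form, no iteration.
.step_dynamic <- function(V_next, ta_i, ps, up, lam, dt, eta0 = 0.2, k_fv = 0.5) {
  pt <- ps$patches
  r <- .shell_radius(V_next, ps$v_wall)
  S <- 4 * pi * r^2
  a_ref <- ps$a_ref
  v_w <- pt$v_w * 1000

  t_stat <- (.sig_pass(lam, up, pt$z) + ta_i * lam^2) * v_w / (a_ref * lam^2)
  h_i <- v_w / (a_ref * lam^2)                       # current thickness (mm)
  eta_t <- (eta0 + k_fv * ta_i) * h_i                # tension-units viscosity
  ci <- dt / eta_t
  bi <- lam - ci * t_stat

  A <- sum(a_ref * ci^2)
  B <- 2 * sum(a_ref * bi * ci)
  C <- sum(a_ref * bi^2) - S
  disc <- B * B - 4 * A * C
  if (disc < 0 || A <= 0) stop("dynamic shell step lost its tension root")
  Tn <- (-B + sqrt(disc)) / (2 * A)                  # right (physical) branch
  lam_new <- pmin(pmax(bi + ci * Tn, 0.4), 2.5)
  p_kpa <- 2 * Tn / r
  list(p = kpa_to_mmhg(p_kpa), lambda = lam_new, tension = Tn, r = r)
}

#' Cavity pressure from the multipatch force balance
#'
#' Given a cavity volume and per-patch active tensions, finds the patch areas
#' that equalize wall tension on the midwall sphere (sum of areas fixed by the
#' volume) and returns the Laplace pressure `p = 2 T / r`.
#'
#' @param V cavity volume (ml).
#' @param ta active tension per patch (kPa), already fibrosis-scaled.
#' @param ps a `patch_set`.
#' @param up a `usyk_params`.
#' @param state optional warm-start state from a previous call.
#' @return List: `p` (mmHg), `lambda` (per-patch stretches), `tension`
#'   (kPa mm), `r` (mm).
#' @export
equilibrium_pressure <- function(V, ta, ps, up = usyk_params(), state = NULL) {
  stopifnot(V > 0)
  ta <- rep_len(ta, nrow(ps$patches))
  .equilibrium(V, ta, ps, up, state = state)
}

# Inverse of equilibrium_pressure in V at fixed tensions: find V with p(V) = p.
.invert_volume <- function(p_target, ta_i, ps, up, V_guess, state = NULL,
                           tol = 1e-4) {
  V <- V_guess
  eqv <- function(Vx, st) .equilibrium(Vx, ta_i, ps, up, state = st)
  eq <- eqv(V, state)
  for (it in 1:60) {
    err <- eq$p - p_target
    if (abs(err) < tol) break
    dV <- max(0.05, 0.002 * V)
    eq2 <- eqv(V + dV, eq)
    slope <- (eq2$p - eq$p) / dV
    if (!is.finite(slope) || slope <= 1e-9) slope <- 1e-2
    step <- -err / slope
    step <- sign(step) * min(abs(step), 0.15 * V)
    V <- max(V + step, 1)
    eq <- eqv(V, eq)
  }
  list(V = V, eq = eq)
}

#' End-diastolic pressure yielding a target EDV
#'
#' Determines the unique filling pressure for which the passive (zero active
#' tension) equilibrium reaches the desired end-diastolic volume, by bisection
#' on the passive pressure-volume curve.
#'
#' @param edv_target target end-diastolic volume (ml).
#' @param ps a `patch_set`.
#' @param up a `usyk_params`.
#' @param tol volume tolerance (ml).
#' @return List: `p_ed` (mmHg) and the achieved volume `v` (ml).
#' @export
find_edp <- function(edv_target, ps, up = usyk_params(), tol = 0.5) {
  if (edv_target <= ps$v0)
    stop(sprintf("infeasible target: EDV %.1f ml is below the unloaded cavity volume %.1f ml",
                 edv_target, ps$v0))
  ta0 <- rep(0, nrow(ps$patches))
  eq <- .equilibrium(edv_target, ta0, ps, up)
  # passive curve is monotone: the pressure at the target volume IS the answer;
  # run the defining bisection on V(p) to honour the volume tolerance
  p_lo <- 0; p_hi <- max(2 * eq$p, 1e-3)
  for (it in 1:80) {
    p_mid <- (p_lo + p_hi) / 2
    v_mid <- .invert_volume(p_mid, ta0, ps, up, V_guess = edv_target)$V
    if (abs(v_mid - edv_target) < tol) break
    if (v_mid < edv_target) p_lo <- p_mid else p_hi <- p_mid
  }
  list(p_ed = p_mid, v = v_mid)
}

#' Simulate one cardiac cycle
#'
#' Phase machine, starting at end-diastole (`V = EDV`, `p = p_ed`):
#' (1) isovolumic contraction - volume fixed, pressure is the equilibrium
#' multiplier, until it reaches the aortic opening pressure `p_d`;
#' (2) ejection - cavity coupled to the two-element Windkessel
#' `C dp/dt = Q - p/R`, `Q = -dV/dt`, until flow reversal;
#' (3) isovolumic relaxation until `p <= p_mvo`;
#' (4) filling - linear pressure ramp from `p_mvo` to `p_ed` over the rest of
#' the beat, volume from equilibrium inversion.
#'
#' @param edv end-diastolic volume (ml).
#' @param ps a `patch_set` (with activation times set).
#' @param traces list of per-patch `tension_trace`s covering the beat.
#' @param up a `usyk_params`.
#' @param wk a `windkessel_params` (uses `p_ed`, `p_d`, `p_mvo`, R, C).
#' @param hr heart rate (beats/min).
#' @param dt time step (s).
#' @param k_fv Hill force-velocity viscosity slope (kPa s per kPa of active
#'   tension): each patch carries a viscous stress `(eta0 + k_fv ta) dlambda/dt`,
#'   so fast shortening sheds active force and fast stretch bears extra, with
#'   the damping proportional to the activation.
#' @param eta0 baseline tissue viscosity (kPa s).
#' @return An object of class `pv_loop`: data.frame `t`, `p` (mmHg), `v` (ml),
#'   `phase`.
#' @export
run_beat <- function(edv, ps, traces, up = usyk_params(), wk = windkessel_params(),
                     hr = 75, dt = 1e-4, k_fv = 0.5, eta0 = 0.2) {
  beat <- 60 / hr
  nt <- as.integer(floor(beat / dt)) + 1L
  tgrid <- (seq_len(nt) - 1) * dt
  ta_mat <- vapply(traces, function(tr) {
    stats::approx(tr$t, tr$ta, xout = tgrid, rule = 2)$y
  }, numeric(nt))                                # nt x N

  p_out <- numeric(nt); v_out <- numeric(nt); phase <- character(nt)
  V <- edv
  st <- .equilibrium(V, ta_mat[1, ], ps, up)
  p_out[1] <- wk$p_ed; v_out[1] <- V; phase[1] <- "isovolumic-contraction"
  k <- 2L
  mode <- 1L
  ramp_t0 <- NA_real_

  while (k <= nt) {
    ta_i <- ta_mat[k, ]
    lam0 <- st$lambda
    stp <- function(Vx) .step_dynamic(Vx, ta_i, ps, up, lam0, dt, eta0, k_fv)
    if (mode == 1L) {                     # isovolumic contraction
      st <- stp(V)
      p_out[k] <- st$p; v_out[k] <- V; phase[k] <- "isovolumic-contraction"
      if (st$p >= wk$p_d) mode <- 2L
    } else if (mode == 2L) {              # ejection (Windkessel coupling)
      p_prev <- p_out[k - 1L]
      g <- function(Vn) {
        pn <- stp(Vn)$p
        wk$C * (pn - p_prev) / dt - (V - Vn) / dt + pn / wk$R
      }
      lo <- V * 0.985; hi <- V * 1.002
      glo <- g(lo); ghi <- g(hi)
      tries <- 0L
      while (glo > 0 && tries < 30L) { hi <- lo; lo <- lo - 0.02 * V; glo <- g(lo); tries <- tries + 1L }
      tries <- 0L
      while (ghi < 0 && tries < 10L) { lo <- hi; hi <- hi + 0.01 * V; ghi <- g(hi); tries <- tries + 1L }
      Vn <- tryCatch(stats::uniroot(g, c(lo, hi), tol = 1e-7)$root,
                     error = function(e) V)
      Q <- (V - Vn) / dt
      if (Q <= 0) {
        mode <- 3L
        st <- stp(V)
        p_out[k] <- st$p; v_out[k] <- V; phase[k] <- "isovolumic-relaxation"
        if (st$p <= wk$p_mvo) { mode <- 4L; ramp_t0 <- tgrid[k] }
      } else {
        V <- Vn
        st <- stp(Vn)
        p_out[k] <- st$p; v_out[k] <- V; phase[k] <- "ejection"
      }
    } else if (mode == 3L) {              # isovolumic relaxation
      st <- stp(V)
      p_out[k] <- st$p; v_out[k] <- V; phase[k] <- "isovolumic-relaxation"
      if (st$p <= wk$p_mvo) { mode <- 4L; ramp_t0 <- tgrid[k] }
    } else {                              # filling: linear pressure ramp
      frac <- (tgrid[k] - ramp_t0) / max(beat - ramp_t0, dt)
      p_ramp <- wk$p_mvo + frac * (wk$p_ed - wk$p_mvo)
      g <- function(Vn) stp(Vn)$p - p_ramp
      lo <- V * 0.97; hi <- V * 1.03
      tries <- 0L
      while (g(lo) > 0 && tries < 40L) { hi <- lo; lo <- lo * 0.97; tries <- tries + 1L }
      tries <- 0L
      while (g(hi) < 0 && tries < 40L) { lo <- hi; hi <- hi * 1.03; tries <- tries + 1L }
      V <- tryCatch(stats::uniroot(g, c(lo, hi), tol = 1e-7)$root,
                    error = function(e) V)
      st <- stp(V)
      p_out[k] <- st$p; v_out[k] <- V; phase[k] <- "filling"
    }
    k <- k + 1L
  }
  if (mode == 1L)
    warning("non-ejecting beat: pressure never reached the aortic opening pressure")
  structure(data.frame(t = tgrid, p = p_out, v = v_out, phase = phase),
            class = c("pv_loop", "data.frame"))
}

#' Chain beats to the limit cycle
#'
#' Runs `n_beats` identical-protocol cycles, each re-filled to the
#' end-diastolic pressure, and returns the final beat's loop with a per-beat
#' summary (the periodic steady state is reached within a few cycles; the
#' final beat is the analysed one).
#'
#' @inheritParams run_beat
#' @param n_beats number of chained cycles.
#' @return List: `loop` (final `pv_loop`), `summary` (per-beat SV/ESV/EDV).
#' @export
run_to_limit_cycle <- function(edv, ps, traces, up = usyk_params(),
                               wk = windkessel_params(), hr = 75, dt = 1e-4,
                               n_beats = 5L, k_fv = 0.5, eta0 = 0.2) {
  stopifnot(n_beats >= 1)
  sv <- esv <- edv_b <- numeric(n_beats)
  loop <- NULL
  V_start <- edv
  for (b in seq_len(n_beats)) {
    loop <- run_beat(V_start, ps, traces, up, wk, hr, dt, k_fv = k_fv, eta0 = eta0)
    esv[b] <- min(loop$v); edv_b[b] <- max(loop$v); sv[b] <- edv_b[b] - esv[b]
    # the filling ramp ends at p_ed; next beat starts from the achieved EDV
    V_start <- loop$v[nrow(loop)]
  }
  list(loop = loop,
       summary = data.frame(beat = seq_len(n_beats), sv = sv, esv = esv,
                            edv = edv_b))
}

#' Clinical biomarkers of a PV loop
#'
#' @param loop a `pv_loop`.
#' @return An object of class `biomarkers`: `edv`, `esv`, `sv` (ml), `ef` (%),
#'   `dpdt_max` (mmHg/s, forward difference over contraction + ejection),
#'   `sw` (mmHg ml, the signed area enclosed by the loop), `p_max` (mmHg).
#' @export
compute_biomarkers <- function(loop) {
  if (nrow(loop) < 3) stop("PV loop needs at least 3 samples")
  edv <- max(loop$v); esv <- min(loop$v)
  sv <- edv - esv
  ef <- 100 * sv / edv
  dt <- diff(loop$t[1:2])
  sys <- which(loop$phase %in% c("isovolumic-contraction", "ejection"))
  sys <- sys[sys < nrow(loop)]
  dpdt_max <- if (length(sys)) max((loop$p[sys + 1L] - loop$p[sys]) / dt) else 0
  # stroke work: area of the closed loop, -contour integral of p dV (shoelace)
  v <- c(loop$v, loop$v[1]); p <- c(loop$p, loop$p[1])
  sw <- -sum((p[-1] + p[-length(p)]) / 2 * diff(v))
  structure(list(edv = edv, esv = esv, sv = sv, ef = ef,
                 dpdt_max = dpdt_max, sw = sw, p_max = max(loop$p)),
            class = "biomarkers")
}

#' @export
print.biomarkers <- function(x, ...) {
  cat(sprintf("EDV %.1f ml  ESV %.1f ml  SV %.1f ml  EF %.1f%%\n",
              x$edv, x$esv, x$sv, x$ef))
  cat(sprintf("dP/dt_max %.0f mmHg/s  SW %.0f mmHg ml  P_max %.1f mmHg\n",
              x$dpdt_max, x$sw, x$p_max))
  invisible(x)
}
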