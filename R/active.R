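# Surrogate excitation-contraction coupling: a heart-rate dependent calcium
# transient and the calcium-driven active-tension transient, shifted in time by
# the local activation and scaled by contractility a_XB and fibrosis z.
#
# The surrogate preserves the two couplings that matter for the reduced model:
# the activation-time shifting of a precomputed per-beat transient, and the
# heart-rate -> calcium-peak -> force inotropy. Full ionic / crossbridge state
# dynamics are deliberately out of scope; constants without a surrogate role
# (gamma, k_basic, mu0_fP, mu1_fP) are carried as inert configuration.

#' Calcium transient parameters
#' @param ca0 diastolic calcium level (uM).
#' @param a_ref reference transient amplitude (uM) at 60 bpm.
#' @param beta heart-rate inotropy slope (dimensionless per 60 bpm).
#' @param tau_r,tau_d rise and decay time constants (s), `tau_r < tau_d`.
#' @return An object of class `calcium_params`.
#' @export
calcium_params <- function(ca0 = 0.1, a_ref = 0.6, beta = 0.5,
                           tau_r = 0.02, tau_d = 0.09) {
  stopifnot(ca0 > 0, a_ref > 0, beta >= 0, tau_r > 0, tau_r < tau_d)
  structure(list(ca0 = ca0, a_ref = a_ref, beta = beta,
                 tau_r = tau_r, tau_d = tau_d), class = "calcium_params")
}

#' Active tension parameters
#'
#' @param a_xb cross-bridge contractility scale (MPa); the surrogate's tension
#'   amplitude, the mechanically calibrated parameter.
#' @param sl0 reference sarcomere length (um).
#' @param kd_bar,alpha_kd calcium sensitivity: `k_d = kd_bar + alpha_kd * (SL -
#'   SL0)` (uM), evaluated at `SL = SL0` in this reduction.
#' @param n_h Hill exponent.
#' @param k_off relaxation rate (1/s).
#' @param extras named list of pass-through constants kept for provenance
#'   (gamma, k_basic, mu0_fP, mu1_fP); unused by the surrogate.
#' @return An object of class `active_tension_params`.
#' @export
active_tension_params <- function(a_xb = 0.08, sl0 = 2.2, kd_bar = 0.4,
                                  alpha_kd = -0.2083, n_h = 2, k_off = 40,
                                  extras = list(gamma = 30, k_basic = 8,
                                                mu0_fP = 32.255, mu1_fP = 0.768)) {
  kd <- kd_bar + alpha_kd * (sl0 - sl0)
  stopifnot(a_xb > 0, kd > 0, n_h >= 1, k_off > 0)
  structure(list(a_xb = a_xb, sl0 = sl0, kd = kd, n_h = n_h, k_off = k_off,
                 extras = extras), class = "active_tension_params")
}

#' Heart-rate dependent calcium transient over one beat
#'
#' `Ca(t) = Ca0 + A(HR) * (exp(-t/tau_d) - exp(-t/tau_r)) / M` with `M`
#' normalizing the bi-exponential bracket to unit peak and
#' `A(HR) = A_ref * (1 + beta * (HR - 60)/60)`: the higher the heart rate, the
#' larger the peak (positive inotropy of rate).
#'
#' @param hr heart rate (beats/min).
#' @param params a `calcium_params`.
#' @param dt sample step (s).
#' @return List with `t` (s) and `ca` (uM) sampled over one beat of length
#'   `60/hr` s.
#' @export
calcium_transient <- function(hr, params = calcium_params(), dt = 1e-4) {
  stopifnot(hr > 0)
  t <- seq(0, 60 / hr, by = dt)
  t_peak <- log(params$tau_d / params$tau_r) /
    (1 / params$tau_r - 1 / params$tau_d)
  M <- exp(-t_peak / params$tau_d) - exp(-t_peak / params$tau_r)
  A <- params$a_ref * (1 + params$beta * (hr - 60) / 60)
  ca <- params$ca0 + A * (exp(-t / params$tau_d) - exp(-t / params$tau_r)) / M
  list(t = t, ca = ca, hr = hr, ca0 = params$ca0)
}

# Hill steady-state permissivity
.p_ss <- function(ca, kd, n_h) ca^n_h / (ca^n_h + kd^n_h)

#' Active tension transient for one patch/element
#'
#' First-order permissivity kinetics driven by the locally shifted calcium
#' transient: `dp/dt = k_off (p_ss(Ca(t - t_act)) - p)`, `p(0) = p_ss(Ca0)`,
#' with Hill steady state `p_ss(Ca) = Ca^n / (Ca^n + k_d^n)`. The tension is
#' `T_a(t) = a_XB * z * (p(t) - p_ss(Ca0))_+` (diastolic offset removed), zero
#' before the local activation time.
#'
#' @param ca calcium trace from [calcium_transient()].
#' @param atp an `active_tension_params`.
#' @param z fibrosis scalar in `[0, 1]` (scales contractility).
#' @param t_act local activation time (s) within the beat.
#' @return List of class `tension_trace`: `t` (s) and `ta` (kPa).
#' @export
active_tension <- function(ca, atp = active_tension_params(), z = 1, t_act = 0) {
  stopifnot(z >= 0, z <= 1)
  t <- ca$t
  dt <- t[2] - t[1]
  beat <- t[length(t)]
  if (t_act >= beat) {
    warning("activation time beyond beat length: patch never activates this beat")
    return(structure(list(t = t, ta = numeric(length(t))), class = "tension_trace"))
  }
  # shifted calcium: diastolic before t_act, transient after (linear interp on grid)
  ts <- t - t_act
  ca_shift <- rep(ca$ca0, length(t))
  pos <- ts >= 0
  ca_shift[pos] <- stats::approx(t, ca$ca, xout = pmin(ts[pos], beat),
                                 rule = 2)$y
  pss <- .p_ss(ca_shift, atp$kd, atp$n_h)
  p0 <- .p_ss(ca$ca0, atp$kd, atp$n_h)
  # exact exponential update per step (p_ss held at the step's left value)
  ef <- exp(-atp$k_off * dt)
  n <- length(t)
  p <- c(p0, as.numeric(stats::filter((1 - ef) * pss[-n], ef,
                                      method = "recursive", init = p0)))
  ta <- atp$a_xb * 1000 * z * pmax(p - p0, 0)   # MPa -> kPa
  structure(list(t = t, ta = ta), class = "tension_trace")
}

#' Read a user-supplied calcium transient
#'
#' CSV override for the surrogate generator: columns `t_s` (time, s) and
#' `ca_uM` (cytosolic calcium, uM). The trace is resampled to the requested
#' step and padded/truncated to one beat at the given heart rate.
#'
#' @param path CSV path with columns t_s, ca_uM.
#' @param hr heart rate (beats/min) defining the beat length.
#' @param dt sample step (s).
#' @return A calcium trace compatible with [active_tension()].
#' @export
read_calcium_trace <- function(path, hr, dt = 1e-4) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "ca_uM") %in% names(df)))
    stop("calcium trace format error: need columns t_s, ca_uM")
  t <- seq(0, 60 / hr, by = dt)
  ca <- stats::approx(df$t_s, df$ca_uM, xout = t, rule = 2)$y
  list(t = t, ca = ca, hr = hr, ca0 = df$ca_uM[1])
}
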