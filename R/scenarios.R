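# Virtual CRT scenario engine: biventricular pacing protocols (left lead along
# the epicardial veins, right lead along the septum, ventriculo-ventricular
# delay), full eikonal + mechanics runs with the personalized parameters, and
# reporting of biomarker changes versus the pre-operative state.

#' Define a CRT scenario
#'
#' @param name scenario label.
#' @param left "LEAS", or `c(branch, arc)` selecting a vein-accessible
#'   position, or an explicit 3-vector (mm).
#' @param right "apical", "mid" or "basal" septal site, or an explicit point.
#' @param vvd ventriculo-ventricular delay (ms); positive values mean the
#'   right stimulation occurs before the left one.
#' @return An object of class `crt_scenario`.
#' @export
crt_scenario <- function(name, left = "LEAS", right = "apical", vvd = 0) {
  if (abs(vvd) > 60) stop("|VVD| must be <= 60 ms")
  structure(list(name = name, left = left, right = right, vvd = vvd),
            class = "crt_scenario")
}

# Resolve the left-lead position to a 3-vector.
.resolve_left <- function(scenario, bundle, psi_pre) {
  lf <- scenario$left
  if (is.character(lf) && identical(toupper(lf), "LEAS")) {
    leas <- find_leas(psi_pre, bundle$veins, bundle$mesh)
    return(as.numeric(leas[1, c("x", "y", "z")]))
  }
  if (is.numeric(lf) && length(lf) == 2) {
    acc <- bundle$veins$accessible
    sel <- acc$branch == lf[1]
    if (!any(sel)) stop("left position: no such vein branch")
    rows <- which(sel)
    i <- rows[which.min(abs(acc$arc[rows] - lf[2]))]
    if (abs(acc$arc[i] - lf[2]) > bundle$veins$step)
      stop("left position: arc length off the vein tree")
    return(as.numeric(acc[i, c("x", "y", "z")]))
  }
  if (is.numeric(lf) && length(lf) == 3) return(as.numeric(lf))
  stop("unresolvable left-lead position")
}

#' Build the biventricular pacing protocol of a scenario
#'
#' Onsets follow the delay convention: `t_left = max(vvd, 0)` ms,
#' `t_right = max(-vvd, 0)` ms, so positive VVD activates the right lead
#' first. The LEAS token resolves against the pre-operative activation map.
#'
#' @param scenario a `crt_scenario`.
#' @param bundle a `patient_bundle`.
#' @param psi_pre pre-operative (calibrated sinus) `activation_map`, used to
#'   resolve the LEAS token.
#' @return List of two `pacing_source`s (left, right).
#' @export
make_pacing_protocol <- function(scenario, bundle, psi_pre) {
  left_pt <- .resolve_left(scenario, bundle, psi_pre)
  right <- scenario$right
  right_src <- if (is.numeric(right) && length(right) == 3) {
    pacing_source(right, onset = 0)
  } else {
    right_lead_source(bundle$mesh, site = right)
  }
  t_left <- max(scenario$vvd, 0) / 1000
  t_right <- max(-scenario$vvd, 0) / 1000
  list(left = pacing_source(left_pt, onset = t_left),
       right = pacing_source(right_src$location, onset = t_right))
}

#' Run one virtual CRT scenario
#'
#' Solves the activation problem with the scenario's two electrodes (pure
#' biventricular capture: the intrinsic septal inputs are disabled unless
#' `fuse_intrinsic`), then runs the personalized mechanics limit cycle with
#' unchanged parameters and preload, and computes the biomarkers of the final
#' beat.
#'
#' @param bundle a `patient_bundle`.
#' @param epcal an `ep_calibration`.
#' @param mechcal a `mech_calibration`.
#' @param scenario a `crt_scenario`, or NULL for the pre-operative reference
#'   (sinus activation, no electrodes).
#' @param psi_pre the calibrated pre-operative `activation_map`.
#' @param fuse_intrinsic logical; also keep the intrinsic septal sources
#'   active during pacing.
#' @param dt,n_beats mechanics settings (defaults from the calibration).
#' @return List of class `scenario_result`: `psi`, `loop`, `biomarkers`.
#' @export
run_scenario <- function(bundle, epcal, mechcal, scenario, psi_pre,
                         fuse_intrinsic = FALSE, dt = NULL, n_beats = NULL) {
  if (is.null(dt)) dt <- mechcal$dt
  if (is.null(n_beats)) n_beats <- mechcal$n_beats
  D <- assemble_conductivity(bundle$fibers, bundle$conductivity,
                             .z_field(bundle, epcal$z))
  epp <- ep_params(c0 = epcal$c0, eps = epcal$eps,
                   z_fibrotic = max(epcal$z, 1e-3))
  if (is.null(scenario)) {
    psi <- psi_pre
    name <- "pre-operative"
  } else {
    proto <- make_pacing_protocol(scenario, bundle, psi_pre)
    sources <- unname(proto)
    if (fuse_intrinsic) sources <- c(sources, bundle$sinus_sources)
    psi <- solve_activation(bundle$mesh, D, sources, epp, curvature_maxit = 8L)
    name <- scenario$name
  }

  ps <- make_patches(bundle$mesh, bundle$aha, .z_field(bundle, epcal$z), psi)
  record <- bundle$record
  ca <- calcium_transient(record$hr, dt = dt)
  atp <- active_tension_params(a_xb = mechcal$a_xb)
  traces <- lapply(seq_len(nrow(ps$patches)), function(i) {
    active_tension(ca, atp, z = ps$patches$z[i], t_act = ps$patches$t_act[i])
  })
  wk <- windkessel_params(R = mechcal$R, p_mvo = min(5, 0.6 * mechcal$p_ed),
                          p_ed = mechcal$p_ed, p_d = record$p_d)
  up <- usyk_params()
  lc <- run_to_limit_cycle(record$edv, ps, traces, up, wk, record$hr, dt, n_beats)
  structure(list(name = name, psi = psi, loop = lc$loop,
                 beats = lc$summary, biomarkers = compute_biomarkers(lc$loop)),
            class = "scenario_result")
}

#' Biomarker deltas versus the pre-operative state
#'
#' Percent change for dP/dt_max, SV and SW; absolute change (percentage
#' points) for EF.
#'
#' @param pre,post `biomarkers` objects.
#' @return Named list `d_dpdt_pct`, `d_sv_pct`, `d_sw_pct`, `d_ef_points`.
#' @export
compute_deltas <- function(pre, post) {
  pc <- function(a, b) {
    if (a == 0) stop("undefined percent change: pre-operative value is zero")
    100 * (b - a) / a
  }
  list(d_dpdt_pct = pc(pre$dpdt_max, post$dpdt_max),
       d_sv_pct = pc(pre$sv, post$sv),
       d_ef_points = post$ef - pre$ef,
       d_sw_pct = pc(pre$sw, post$sw))
}

#' Sweep one scenario axis
#'
#' Runs the pre-operative reference plus one scenario per value of the swept
#' axis (left-lead position, right-lead site, or VVD), holding the other
#' coordinates at their defaults (left = LEAS, right = apical, VVD = 0), and
#' reports biomarkers with deltas in the standard convention.
#'
#' @param bundle,epcal,mechcal,psi_pre as in [run_scenario()].
#' @param axis "left", "right" or "vvd".
#' @param values axis values: left = list of vein positions (or "LEAS");
#'   right = character sites; vvd = delays in ms (default
#'   `c(-30, -15, 0, 15, 30)`).
#' @param ... passed to [run_scenario()].
#' @return An object of class `scenario_report`: data.frame with one row per
#'   scenario (pre-operative first, all deltas zero there).
#' @export
sweep_scenarios <- function(bundle, epcal, mechcal, psi_pre,
                            axis = c("vvd", "left", "right"), values = NULL, ...) {
  axis <- match.arg(axis)
  if (is.null(values)) {
    values <- switch(axis,
                     vvd = c(-30, -15, 0, 15, 30),
                     right = c("apical", "mid", "basal"),
                     left = { acc <- bundle$veins$accessible
                              idx <- which(acc$arc %% 10 < bundle$veins$step &
                                             acc$branch > 1)
                              c(list("LEAS"),
                                lapply(idx[seq_len(min(3, length(idx)))],
                                       function(i) c(acc$branch[i], acc$arc[i]))) })
  }
  pre <- run_scenario(bundle, epcal, mechcal, NULL, psi_pre, ...)
  rows <- list(.report_row("pre-operative", pre$biomarkers,
                           list(d_dpdt_pct = 0, d_sv_pct = 0,
                                d_ef_points = 0, d_sw_pct = 0)))
  vals <- if (is.list(values)) values else as.list(values)
  for (v in vals) {
    sc <- switch(axis,
                 vvd = crt_scenario(sprintf("VVD %+d ms", as.integer(v)), vvd = v),
                 right = crt_scenario(paste0("right ", v), right = v),
                 left = crt_scenario(
                   if (is.character(v)) "LEAS" else
                     sprintf("vein %d @ %.0f mm", v[1], v[2]), left = v))
    row <- tryCatch({
      res <- run_scenario(bundle, epcal, mechcal, sc, psi_pre, ...)
      .report_row(sc$name, res$biomarkers,
                  compute_deltas(pre$biomarkers, res$biomarkers))
    }, error = function(e) {
      r <- .report_row(sc$name, NULL, NULL)
      r$status <- paste("failed:", conditionMessage(e))
      r
    })
    rows <- c(rows, list(row))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("scenario_report", "data.frame"))
}

.report_row <- function(name, bm, deltas) {
  if (is.null(bm)) {
    return(data.frame(scenario = name, dpdt_max = NA_real_, sv = NA_real_,
                      ef = NA_real_, sw = NA_real_, d_dpdt_pct = NA_real_,
                      d_sv_pct = NA_real_, d_ef_points = NA_real_,
                      d_sw_pct = NA_real_, status = "failed"))
  }
  data.frame(scenario = name, dpdt_max = bm$dpdt_max, sv = bm$sv, ef = bm$ef,
             sw = bm$sw, d_dpdt_pct = deltas$d_dpdt_pct,
             d_sv_pct = deltas$d_sv_pct, d_ef_points = deltas$d_ef_points,
             d_sw_pct = deltas$d_sw_pct, status = "ok")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("CRT scenario report (deltas vs pre-operative: % for dP/dt_max, SV, SW;\n")
  cat("percentage points for EF)\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}
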