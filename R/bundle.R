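# Synthetic patient bundles: the package's study conditions. A bundle carries
# everything the personalization and scenario engines consume for one virtual
# patient - geometry, microstructure, fibrosis, veins, truth activation maps,
# simulated mapping clouds and the clinical summary record.

#' Default synthetic patient summary record
#'
#' Volumes, pressures and heart rate of a dilated non-fibrotic LBBB ventricle
#' (EDV 350 ml, EF 32%, arm pressures 75/140 mmHg, HR 75 bpm), the magnitudes
#' typical of the CRT candidates the framework targets.
#'
#' @param fibrotic logical; flips the record's fibrosis flag.
#' @return A one-row `patient_record` data.frame.
#' @export
default_patient_record <- function(fibrotic = FALSE) {
  rec <- data.frame(patient_id = "SYN1", fibrotic = fibrotic, nyha_class = 3L,
                    esv = 238, edv = 350, sv = 112, ef = 32.0,
                    p_d = 75, p_s = 140, hr = 75)
  validate_patient_records(rec)
}

#' Generate a synthetic patient bundle
#'
#' Builds the full virtual-patient input set: truncated-ellipsoid LV mesh with
#' rule-based fibres and AHA segmentation, bullseye fibrosis field, procedural
#' epicardial vein tree, a left-bundle-branch-block truth activation map
#' (septal sources only), simulated EAMS clouds for sinus rhythm and right
#' pacing, and a clinical summary record.
#'
#' @param seed integer; all randomness in the bundle flows from it.
#' @param fibrotic logical; when TRUE the default bullseye marks the
#'   (infero)lateral segments with `z = z_fibrotic`.
#' @param bullseye optional explicit bullseye (overrides `fibrotic` default).
#' @param z_fibrotic fibrosis factor of the marked segments.
#' @param record patient summary record; default [default_patient_record()].
#' @param mesh_h target mesh edge length (mm).
#' @param c0,eps truth eikonal parameters of the bundle.
#' @param sigma_f truth fibre conductivity (m^2/s).
#' @param noise_sd EAMS time-noise standard deviation (s).
#' @param counts EAMS points per region (see [synthesize_eams()]).
#' @return An object of class `patient_bundle`.
#' @export
synth_patient_bundle <- function(seed = 1L, fibrotic = FALSE, bullseye = NULL,
                                 z_fibrotic = 0.7, record = NULL,
                                 mesh_h = 4, c0 = 80, eps = 0,
                                 sigma_f = 2.0e-4, noise_sd = 0.005,
                                 counts = c(septum = 10, cs = 40, lateral = 30)) {
  if (is.null(record)) record <- default_patient_record(fibrotic)
  mesh <- build_lv_mesh(target_h = mesh_h)
  fibers <- generate_fibers(mesh)
  aha <- aha_segments(mesh)
  if (is.null(bullseye)) {
    bullseye <- if (fibrotic)
      stats::setNames(as.list(rep(z_fibrotic, 4)), c(5, 11, 12, 16)) else list()
  }
  fib <- make_fibrosis_field(mesh, aha, bullseye)
  veins <- generate_vein_tree(mesh, seed = seed)

  cp <- conductivity_params(sigma_f = sigma_f)
  ep <- ep_params(c0 = c0, eps = eps,
                  z_fibrotic = if (fibrotic) z_fibrotic else 1)
  D <- assemble_conductivity(fibers, cp, fib)

  sinus_sources <- septal_sources(mesh)
  psi_sinus <- solve_activation(mesh, D, sinus_sources, ep)

  rp_sources <- list(right_lead_source(mesh, site = "apical"))
  psi_rp <- solve_activation(mesh, D, rp_sources, ep)

  eams_sinus <- synthesize_eams(psi_sinus, mesh, veins, counts = counts,
                                noise_sd = noise_sd, seed = seed)
  eams_rp <- synthesize_eams(psi_rp, mesh, veins,
                             counts = c(septum = 0, cs = min(counts[["cs"]], 30),
                                        lateral = 0),
                             noise_sd = noise_sd, seed = seed + 1000L)

  structure(list(
    seed = as.integer(seed), record = record,
    mesh = mesh, fibers = fibers, aha = aha, fibrosis = fib, veins = veins,
    conductivity = cp, ep_truth = ep,
    sinus_sources = sinus_sources, rp_sources = rp_sources,
    psi_sinus = psi_sinus, psi_rp = psi_rp,
    eams_sinus = eams_sinus, eams_rp = eams_rp
  ), class = "patient_bundle")
}

#' @export
print.patient_bundle <- function(x, ...) {
  cat(sprintf("Synthetic patient bundle '%s' (seed %d, %s)\n",
              x$record$patient_id, x$seed,
              if (x$record$fibrotic) "fibrotic" else "non-fibrotic"))
  print(x$mesh)
  print(x$eams_sinus)
  invisible(x)
}

#' Septal surrogate sources for the sinus (LBBB) protocol
#'
#' Three equispaced points on the right-facing septal surface, mimicking the
#' residual right-sided conduction entry during left bundle branch block. The
#' points sit on the apical half of the septum (the His-Purkinje breakthrough
#' region); the basal and lateral walls then activate last, the hallmark of
#' LBBB dyssynchrony.
#'
#' @param mesh an `lv_mesh`.
#' @param onsets onset times (s) of the three points.
#' @return List of `pacing_source`s.
#' @export
septal_sources <- function(mesh, onsets = c(0, 0, 0)) {
  ab <- c(0.2, 0.35, 0.5)
  pts <- shell_point(mesh, 1, ab, rep(0, 3))    # septal epicardium, theta = 0
  lapply(1:3, function(k) pacing_source(pts[k, ], onset = onsets[k]))
}

#' Right-lead pacing source at a septal site
#'
#' The right electrode is represented on the septal LV epicardium (standing in
#' for the right-ventricular septal endocardium): "apical" near the apex below
#' the septum, "mid" halfway apex-base, "basal" in the upper third.
#'
#' @param mesh an `lv_mesh`.
#' @param site "apical", "mid" or "basal", or a numeric apicobasal coordinate.
#' @param onset onset time (s).
#' @return A `pacing_source`.
#' @export
right_lead_source <- function(mesh, site = "apical", onset = 0) {
  ab <- if (is.numeric(site)) site else
    switch(match.arg(site, c("apical", "mid", "basal")),
           apical = 0.12, mid = 0.5, basal = 0.75)
  pacing_source(shell_point(mesh, 1, ab, 0), onset = onset)
}
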