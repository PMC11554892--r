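---
title: "Personalized eikonal-reaction-mechanics simulation of CRT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized eikonal-reaction-mechanics simulation of CRT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crtsim` is a desk-scale framework for planning cardiac resynchronization
therapy (CRT) in silico: it builds a synthetic left ventricle (LV) with
fibres, fibrosis and epicardial veins; solves an anisotropic eikonal problem
for activation times; couples an activation-shifted active-tension surrogate
to a reduced multipatch mechanics model with a two-element Windkessel
afterload; personalizes the electrical and mechanical parameters against
mapped activation times and clinical pressure/volume summaries; and sweeps
virtual electrode positions and inter-ventricular delays, scoring each
scenario with the standard acute biomarkers (dP/dt max, stroke volume,
ejection fraction, stroke work).

This vignette documents the models, their assumptions, the numerical choices,
and the known limitations. Nothing stated here goes beyond what the package's
tests and acceptance script themselves compute.

## Synthetic anatomy

The LV is a truncated-ellipsoid hexahedral shell between two centred
ellipsoids (`build_lv_mesh()`). Defaults: endocardial semi-axes
31.5/31.5/68 mm, wall thickness 9.5 mm, base plane at a polar angle of
1.833 rad from the apex, giving a cavity of about 195 ml and a wall of about
169 ml — a dilated cardiomyopathy ventricle sized so that passive inflation
to the default patient's end-diastolic volume (350 ml) lands at a realistic
filling pressure of a few mmHg. A small apical opening (2.5 mm radius) keeps
every hexahedron non-degenerate; its effect on cavity volume is below the 2%
agreement demanded of the analytic-volume oracle. Normalized transmural,
apicobasal and circumferential coordinates come directly from the
parameterization, so no Laplace solves are needed.

Rule-based fibres rotate linearly across the wall from +60 degrees at the
endocardium to -60 degrees at the epicardium (sheet angle 20/20). The printed
angle pair carries no signs; the conventional counter-rotation was chosen and
is asserted (with an independent finite-difference frame) in the tests. AHA-17
segmentation is a pure function of the normalized coordinates (basal ring
above 2/3 apicobasal, mid 1/3-2/3, four apical sectors 1/9-1/3, apical cap
below 1/9; circumferential zero at the mid-septum). Fibrosis is a bullseye:
segment to factor z in [0,1], z = 1 healthy, constant within a segment.

The epicardial vein tree is procedural (no vein geometry is printed
anywhere): a coronary-sinus trunk circles the base and 2-4 tributaries
descend the lateral/anterolateral wall, as natural cubic splines through
points sampled on the analytic epicardial surface, resampled every 2 mm of
arc length. These arc-length samples are the anatomically accessible left
electrode positions.

Simulated electro-anatomical (EAMS) clouds sample the septal endocardium, the
vein tree ("cs" region) and the lateral epicardium, with counts (10/40/30 by
default) emulating clinical acquisition sizes. Noise is additive Gaussian on
the times only (5 ms standard deviation by default, truncated at three
standard deviations); positions are exact. Cloud-to-geometry alignment uses
three matched reference pairs, a closed-form rigid (Kabsch) fit, and
nearest-facet surface projection.

## Activation: anisotropic eikonal solver

Front arrival times psi solve `c0 * sqrt(grad psi' D grad psi) = 1` with the
fibrosis-scaled normalized conductivity tensor

    D = z sigma_s I + z (sigma_f - sigma_s) f f' + z (sigma_n - sigma_s) n n'.

The anisotropy ratios are fixed (sigma_s/sigma_f = 0.458, sigma_n/sigma_f =
0.148, constant across published personalizations), so the electrical
calibration exposes a single front-rate magnitude c0 (s^-1/2).

The solver works on the 6-tetrahedron split of the hexahedral mesh with a
label-correcting fast-iterative scheme. The local solver combines the
linear-wavefront face update (exact for planar fronts; accepted only when the
upwind characteristic crosses the face interior) with closed-form edge and
vertex fallbacks. Sources capture all nodes within 1.5 mm at their onset;
a surrounding factorization ball (radius `max(3 mm, 5h)`) is initialized with
the exact local-metric arrival time, because the front-curvature error of a
raw point source otherwise dominates the error budget (4-5% far-field
worst-case against the analytic solution, versus under 2% with
factorization). On analytic benchmarks the solver reproduces planar speeds
`c0 sqrt(u' D u)` to within discretization error and converges at first
order.

The curvature weight eps enters as a fixed-point correction
`c0 sqrt(grad psi' D grad psi) = 1 + eps * div(D grad psi)`, damped 50% per
iteration and stopped at a 0.1 ms update or 20 iterations. The flux form
`div(D grad psi)` (a dimensionless quantity for D in m^2/s) was chosen over a
normalized-flux variant because only it is compatible with dimensionless
weights of order 10 producing the mild curvature effect the parameter is
meant to control; expanding fronts slow down, colliding fronts speed up.

The latest electrically activated segment (LEAS) is the vein-accessible
position with maximal interpolated psi, ties broken towards the lowest
(branch, arc-length) pair.

## Excitation-contraction surrogate

The full ionic and crossbridge models are deliberately not reproduced; the
surrogate keeps exactly the couplings the downstream mechanics uses:

* a heart-rate dependent calcium transient
  `Ca(t) = Ca0 + A(HR) (exp(-t/tau_d) - exp(-t/tau_r)) / M`, peak-normalized,
  with `A(HR) = A_ref (1 + beta (HR - 60)/60)` — higher rate, higher peak
  (positive force-frequency);
* first-order permissivity kinetics
  `dp/dt = k_off (p_ss(Ca(t - t_act)) - p)` with Hill steady state
  (`n_H = 2`, `k_d = 0.4 uM` at the reference sarcomere length, `k_off = 40/s`),
  driven by the *locally shifted* calcium transient — this is how the
  activation map enters the mechanics;
* tension `T_a = a_XB * z * (p - p_diastolic)+`, linear in the contractility
  scale `a_XB` (the mechanically calibrated parameter) and the fibrosis
  factor z.

Defaults: `Ca0 = 0.1 uM`, `A_ref = 0.6 uM`, `beta = 0.5`, `tau_r = 0.02 s`,
`tau_d = 0.09 s`. The decay constant was set so that the tension transient
returns below 1% of its peak before the end of the beat at the fastest
clinical heart rate handled (110 bpm) — with `tau_d = 0.11 s` a residual Hill
drive of about 1.5% of peak persists at that rate, violating the relaxation
property the model is required to have. Constants of the replaced crossbridge
model with no role in the surrogate (gamma, k_basic, mu0_fP, mu1_fP) are
carried as inert configuration for provenance.

## Reduced multipatch mechanics

The largest deliberate departure from a 3D finite-element model: the LV wall
is reduced to N = 17 thick-membrane patches (one per AHA segment) on a
spherical midwall shell. Each patch carries its wall volume, reference
midwall area fraction, mean fibrosis and volume-weighted mean activation
time. At cavity volume V the midwall radius is
`r = (3(V + V_wall/2) / 4 pi)^(1/3)`; patch areas redistribute under a common
wall tension T, and the cavity pressure is the Laplace pressure `p = 2 T / r`.

Per patch, the tension is (stress times current thickness
`h = V_w / (A_ref lambda^2)`):

* passive: uniaxial fibre-direction Cauchy stress from the exponential
  strain energy `W = C/2 (e^Q - 1)`,
  `Q = b_f E_ff^2 + (b_s + b_n) E_tt^2` under isochoric uniaxial kinematics,
  scaled by the fibrotic stiffening factor `z + (1 - z) * 4.56`;
* active: the surrogate tension, treated as a fibre-direction second
  Piola-Kirchhoff stress and pushed forward to Cauchy (`lambda^2` factor at
  J = 1). The push-forward matters: adding the tension as Cauchy stress
  directly makes patch tension non-monotone in stretch (the active term
  then scales as `1/lambda^2` through the thickness) and lets
  early-activated patches shorten without bound;
* viscous: a Kelvin-Voigt stress `(eta0 + k_fv * ta) dlambda/dt` with
  `k_fv = 0.5 s` and a minimal baseline `eta0 = 0.2 kPa s`. The
  activation-proportional part is the reduction's Hill force-velocity
  relation — the crossbridge model this package surrogates has these dynamics
  built in. Without it the shell is a pure pressure source: systolic pressure
  becomes insensitive to the afterload resistance (destroying the
  two-parameter mechanical calibration) and dyssynchrony *raises* stroke
  volume, inverting the premise of resynchronization.

Numerically, the patch stretches are explicit dynamic states:
`eta_i h_i dlambda_i/dt = T - T_i(lambda_i)`. Advancing lambda explicitly
makes the spherical area constraint a scalar quadratic in T, solved in closed
form at every time step (the physical root is the right branch of the
parabola) — no per-step iteration. The explicit treatment of the passive
stress is stable for `dt` well above the default `1e-4 s` (the stability
bound `eta0 h / (dT/dlambda)` sits near `2e-3 s` at physiological operating
stretches). Static queries (the unloaded state, the passive
pressure-volume curve, the exported `equilibrium_pressure()`) use a
guaranteed nested solver: per-patch bracketed Newton inside, bisection on the
common tension outside, with the tension bracketed by the patch tensions at
the area-equalizing stretch.

The cardiac cycle is the four-phase machine: isovolumic contraction (volume
fixed, pressure is the equilibrium multiplier) until the aortic opening
pressure — surrogated, as in the clinical protocol, by the measured diastolic
arm pressure P_D; ejection coupled to the two-element Windkessel
`C dp/dt = Q - p/R` until flow reversal; isovolumic relaxation to the mitral
opening pressure; and a linear pressure ramp back to the end-diastolic
pressure over the remainder of the beat, with volume from inversion of the
dynamic balance. The end-diastolic pressure is determined per patient as the
unique pressure at which the passive ventricle reaches the measured EDV
(bisection to 0.5 ml). The mitral opening pressure is
`min(5 mmHg, 0.6 p_ED)` — the reference value of 5 mmHg, guarded so it stays
below soft end-diastolic pressures. Five chained beats reach a periodic
state; the final beat is analysed. Simulations at `dt = 2.5e-4 s` are used
throughout the test-suite problem sizes; results there are insensitive to
halving the step.

Biomarkers from the final loop: EDV/ESV as volume extrema, SV, EF, dP/dt max
as the maximal forward difference over contraction + ejection, and stroke
work as the (shoelace) area of the closed PV loop, cross-checked in the tests
against the independent `integral p (-dV/dt) dt` oracle.

## Personalization

**Electrical.** The calibration error is
`e[%] = 100 sum|t_clin - t_comp| / (N T_max)`, with `T_max` the maximum
*clinically recorded* time of the comparison at hand (applied uniformly to
calibration, validation, and the cross errors). Coordinate descent follows
the clinically documented order: golden-section on c0 (bracket 40-140,
tolerance 0.5), then the curvature weight (coarse grid, golden refinement
only when the grid shows a real benefit — at least 0.1 percentage points —
since each curvature evaluation costs several eikonal solves), then, for
fibrotic patients, a grid over z in {0.5, ..., 1.0}; at most two sweeps;
converged iff the final error is below 10%. Each z candidate reuses the
current (c0, eps) rather than re-optimizing them per z (one refinement pass
covers the interaction). On a noise-free synthetic cloud the procedure
recovers the true c0 to a fraction of a percent; with 5 ms noise on 40
coronary-sinus points the final error settles near 3%, comfortably inside
the 10% criterion.

**Validation.** Right pacing (single apical septal source) is simulated with
the calibrated parameters; the validation error compares it against the
right-pacing cloud. Two control errors certify the protocols differ: e_I
(right-pacing cloud vs the *sinus* simulation) and e_II (sinus cloud vs the
*right-pacing* simulation); both must be large relative to the validation
error for the cross-validation to mean anything.

**Mechanical.** With the activation map fixed and the preload determined,
contractility a_XB and Windkessel resistance R are fitted to the two
remaining targets, ESV and systolic pressure P_S. The external PV-loop
emulator workflow is replaced by an internal local-linear surrogate: a small
full-model design (one perturbation per parameter) estimates the 2x2
response Jacobian, Newton-style steps are verified with full limit-cycle
runs, and the Jacobian is refreshed by Broyden updates. Success requires
residuals within 1 ml and 1 mmHg; self-generated targets are recovered to
within 2% in both parameters. The passive stiffness is never calibrated.

## CRT scenarios

Scenario coordinates: left lead (LEAS token or any vein-accessible
position), right lead (apical phi_ab = 0.12, mid 0.5, basal 0.75 on the
septal wall), and the ventriculo-ventricular delay VVD (positive = right lead
first; onsets `t_left = max(VVD, 0)`, `t_right = max(-VVD, 0)`). During CRT
the intrinsic septal inputs are disabled (pure biventricular capture) — an
intrinsic LBBB beat would otherwise still dominate the early septum; a
`fuse_intrinsic` flag restores fusion for sensitivity studies. Personalized
parameters and the preload (p_ED, EDV) are reused unchanged from the
pre-operative state, the standard acute-phase assumption. Reports follow the
clinical table convention: percent change for dP/dt max, SV and SW; absolute
percentage points for EF.

## Study conditions of the synthetic default patient

The default summary record is a dilated non-fibrotic LBBB ventricle: ESV
238 ml, EDV 350 ml, EF 32%, arm pressures 75/140 mmHg, HR 75 bpm —
mid-range magnitudes for CRT candidates. The LBBB truth places three
equispaced surrogate sources on the *apical half* of the right-facing septum
(phi_ab 0.2/0.35/0.5), the His-Purkinje breakthrough region, so the basal
and lateral walls activate last. This placement matters on a rotationally
symmetric synthetic ventricle: sources spread over the full septal height
make the sinus and biventricular-pacing activation patterns near mirror
images, and no pacing protocol could then improve anything. The fibrotic
twin marks the (infero)lateral segments (5, 11, 12, 16) at z = 0.7.

## What the synthetic data do and do not show

The generator emulates acquisition counts, activation-time ranges, noise
levels and the clinical summary quantities. It does not emulate real
anatomical asymmetry (the synthetic LV has equal short semi-axes and uniform
wall thickness), real scar geometry (fibrosis is segment-constant), mapping
position error (noise is on times only), or the right ventricle. Passing
tests therefore demonstrate that the algorithms are implemented correctly
and respond in the physically expected directions under controlled
conditions — not that the pipeline is clinically validated.

A concrete consequence, measured and deliberately left visible in the
acceptance suite: with the apical right lead and the lateral LEAS lead, the
volume-weighted activation-time dispersion across the 17 patches is
essentially the same as under LBBB on this symmetric anatomy (the late
region moves from the basal-lateral to the basal-septal wall). dP/dt max in
the reduction is the peak aggregate force rate — a convolution of the
activation-time density with the twitch rise kernel — so it cannot increase
when the dispersion does not shrink, and the directional check on dP/dt max
fails while SV, EF and SW improve as expected. Reproducing the printed
dP/dt max gains would require the asymmetric anatomy (thicker lateral wall,
a true right ventricle) that the desk-scale reduction deliberately omits.

## Numerical choices at a glance

* Mesh: structured resolution from a target edge length; default bundles use
  4 mm (electrophysiology accuracy checks run on boxes at 0.8 mm).
* Eikonal: label-correcting sweeps to a 1e-12 s improvement tolerance;
  curvature fixed point damped 0.5, tolerance 0.1 ms, max 20 iterations.
* Mechanics: dt = 1e-4 s default (2.5e-4 in the test problem sizes), five
  beats, explicit viscous patch dynamics with closed-form tension root;
  static balances solved to 1e-10 relative.
* Calibration: golden-section tolerances 0.5 (c0) and 1.0 (eps); z grid step
  0.1; mechanical fit residual targets 1 ml / 1 mmHg, iteration cap 8.
* Degenerate inputs are rejected early: zero wall thickness, collinear
  registration points, empty clouds, non-conducting regions containing no
  source, infeasible EDV targets below the unloaded volume.

## Reproducibility

Every stochastic step (vein azimuths, EAMS sampling, noise) flows from the
bundle seed; two bundles with equal seeds are bit-identical, and the
scenario engine is fully deterministic given a bundle and calibration.
`scripts/acceptance.R --seed N --out results/acceptance.json` regenerates
the headline electrical-calibration result from scratch.
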