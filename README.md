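# crtsim

Desk-scale, personalized **eikonal–reaction–mechanics** simulation of cardiac
resynchronization therapy (CRT).

Roughly a third of heart-failure patients with left bundle branch block
(LBBB) do not respond to CRT, and there is no agreed rule for where to place
the two pacing electrodes or how to stagger their stimuli. `crtsim` is an R
package for exploring that question in silico on synthetic left ventricles:
it personalizes an electro-mechanical ventricle model against the kind of
data a cardiologist acquires during the implantation procedure
(electro-anatomical mapping points with activation times, plus routine
volumes and pressures), cross-validates the electrical personalization
against a second pacing protocol, and then compares virtual CRT scenarios —
left lead anywhere along the epicardial veins (including the latest
electrically activated segment, LEAS), right lead along the septum, and
ventriculo-ventricular delays — through the acute clinical biomarkers
dP/dt<sub>max</sub>, stroke volume (SV), ejection fraction (EF) and stroke
work (SW).

The modelling core:

* **Activation.** Anisotropic eikonal equation
  `c0 * sqrt(grad ψ' D grad ψ) = 1` on a hexahedral LV mesh, with the
  fibrosis-scaled normalized conductivity tensor
  `D = z σ_s I + z(σ_f − σ_s) f f' + z(σ_n − σ_s) n n'`, rule-based fibre
  triads `(f, s, n)`, an optional curvature-weight correction, and a
  fast-iterative tetrahedral solver with source factorization.
* **Excitation–contraction.** A heart-rate-dependent calcium transient
  (higher rate → higher peak) drives Hill-kinetics permissivity; the active
  tension `T_a = a_XB · z · (p − p_diastolic)+` is shifted in time by the
  local activation ψ.
* **Mechanics.** A 17-patch (AHA segment) thick-membrane spherical shell:
  patch areas redistribute under a common wall tension, cavity pressure is
  the Laplace pressure `p = 2T/r`, patches carry Usyk-type passive stress
  with fibrotic stiffening `z + (1−z)·4.56` and an activation-proportional
  force–velocity viscosity. The cycle runs the four-phase machine
  (isovolumic contraction → Windkessel-coupled ejection → isovolumic
  relaxation → linear-ramp filling) for five beats to a limit cycle.
* **Personalization.** Electrical: coordinate descent (c0, then the
  curvature weight, then the fibrosis factor z) minimizing the relative
  activation-time error `e[%] = 100 Σ|t_clin − t_comp| / (N T_max)` on the
  coronary-sinus mapping cloud, converged iff `e < 10%`; validated against
  right pacing. Mechanical: contractility a_XB and Windkessel resistance R
  fitted to ESV and systolic pressure with a local-linear surrogate and
  full-model verification.

Real patient data of this kind are not public, so the package ships a
first-class synthetic-patient generator (`synth_patient_bundle()`): geometry,
fibres, AHA-17 bullseye fibrosis, a procedural epicardial vein tree, truth
activation maps and noisy simulated mapping clouds, all reproducible from a
single seed. See the methods vignette (`vignettes/crtsim-methods.Rmd`) for
the models, assumptions and limitations.

## Worked example

Generate a synthetic LBBB patient, personalize the electrical model against
its noisy coronary-sinus cloud, and cross-validate against right pacing:

```r
library(crtsim)

b <- synth_patient_bundle(seed = 1)
b
#> Synthetic patient bundle 'SYN1' (seed 1, non-fibrotic)
#> LV hexahedral mesh
#>   nodes: 5580   elements: 3600   mean edge: 3.58 mm
#>   structured dims (nt x nab x nc): 2 x 30 x 60
#>   cavity volume: 194.6 ml   wall volume: 168.7 ml
#> EAMS cloud: 80 points (cs 40, lateral 30, septum 10); AT range [0.006, 0.114] s

cal <- calibrate_ep(b)
cal
#> EP calibration: c0 = 79.82 s^-1/2, eps = 0.00, z = 1.00; e = 3.18% (converged)

cross_validate(b, cal)
#> Validation error 3.2%; e_I 17.3%, e_II 15.6%
```

What the numbers mean: the bundle's activation truth was generated with
`c0 = 80 s^-1/2`, and the calibration recovers `79.82` from 40 noisy
(5 ms sd) mapping points, with a final activation-time error of 3.18% —
well inside the 10% convergence criterion. The right-pacing validation error
(3.2%) is small while the cross errors e_I and e_II (right-pacing data vs the
sinus simulation and vice versa) are five times larger: the two protocols
carry genuinely different information, so the validation is meaningful.

From here, `find_edp()` + `calibrate_mech()` personalize the mechanics, and
`run_scenario()` / `sweep_scenarios()` compare CRT configurations:

```r
psi  <- b$psi_sinus                       # calibrated sinus activation map
mech <- calibrate_mech(b, psi)
rep  <- sweep_scenarios(b, cal, mech, psi, axis = "vvd")
rep   # pre-operative row first; % deltas for dP/dt_max, SV, SW; EF in points
```

A thin command-line front end over the same functions lives in
`inst/cli/crtsim.R` (`synth`, `ep-calibrate`, `ep-validate`,
`mech-calibrate`, `simulate`, `sweep-left`, `sweep-right`, `sweep-vvd`,
`report`).

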