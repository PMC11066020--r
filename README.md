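# bulbflow

Hemodynamic biomarkers of pro-thrombotic flow in the carotid bifurcation
bulb, computed from time-resolved 3D velocity fields on tetrahedral
meshes.

Shelf-like webs in the internal carotid artery (ICA) bulb are associated
with cryptogenic stroke; the proposed mechanism is flow stasis — a slow
recirculation pocket downstream of the web that persists through the
cardiac cycle, putting blood in the low-shear regime
(γ ≲ 10 s⁻¹) where the coagulation cascade activates. `bulbflow` is an R
toolkit for quantifying that regime, aimed at cardiovascular
biomechanics researchers post-processing CFD or 4D-flow-style velocity
fields:

* **Wall metrics** — wall shear stress by near-wall probing, shear rate
  γ = |τ|/μ, TAWSS, oscillatory shear index
  OSI = ½(1 − ‖∫τ dt‖ / ∫‖τ‖ dt) ∈ [0, 0.5], relative residence time
  RRT = 1/((1 − 2 OSI)·TAWSS), and thresholded area fractions
  (low-shear area below 10 s⁻¹, high-OSI area above a pooled top-1%
  threshold) inside the bulb region of interest.
* **Volumetric metrics** — low-velocity volume fractions per cardiac
  frame and **stasis**: the percentage of the cycle during which a
  low-velocity region (default threshold 3 cm/s) is present in the bulb.
* **Geometry** — centerline extraction by cross-section-centroid
  marching, lumen radius profiles, ECST-style percent narrowing, and the
  bulb ROI from the narrowest lumen point (or the bifurcation) to 1.5
  CCA diameters downstream.
* **Boundary conditions** — subject-specific RCR Windkessel outlets:
  R_total = MAP/Q̄, C_total = SV/PP, Murray's-law (d^2.1) outflow
  splitting, and a 0D RK4 pressure-response check.
* **Cohort statistics** — ROC/AUC/Gini threshold-sensitivity sweeps and
  Kruskal–Wallis tests with Dunn pairwise comparisons.
* **Synthetic generator** — idealized tubes and carotid bifurcations
  (optionally with a web-like focal narrowing), pulsatile parabolic flow
  with exact analytic oracles, programmable recirculation pockets, and
  seeded three-group cohorts, so the entire pipeline is testable without
  patient data.

File formats: legacy ASCII VTK unstructured grids (mesh + velocity
frames), ASCII STL surfaces, CSV waveforms, YAML vitals.

## Worked example

Build a synthetic web subject, find its bulb, and score its stasis:

```r
library(bulbflow)

# idealized carotid bifurcation with a 30% web in the proximal ICA
spec <- bifurcation_spec(web = list(narrowing_fraction = 0.3,
                                    shelf_axial_position = 0.4))
mesh <- make_bifurcation_mesh(spec, mesh_resolution(n_radial = 8,
                                                    n_circumferential = 16,
                                                    n_axial = 8,
                                                    boundary_layers = 0,
                                                    coarse_wall_fraction = 0.25),
                              n_axial_ica = 36)

# pulsatile parabolic field driven by a carotid-like waveform
wf <- make_carotid_waveform(period = 0.9, mean_flow = 6, peak_flow = 11.4)
field <- sample_parabolic_field(mesh, wf, n_frames = 20)

# a recirculation pocket that dwells below 2.8 cm/s for 95% of the cycle
pocket <- recirculation_spec(pocket_center = c(0.35, 0, 2.55),
                             pocket_radius = 0.12, peak_speed = 2.8,
                             dwell_fraction = 0.95,
                             swirl_axis = c(sin(25 * pi / 180), 0,
                                            cos(25 * pi / 180)))
field <- add_recirculation_pocket(field, mesh, pocket, waveform = wf)

# geometry: centerline, CCA diameter, bulb ROI
cl <- extract_centerline(mesh, target = "outlet_ica")
D <- cca_diameter(cl)
roi <- clip_bulb_roi(mesh, cl, lesion_arclength = 2.4, cca_diameter = D)

curve <- volume_fraction_curve(field, mesh, roi, threshold = 3)
stasis_pct(curve)
#> [1] 95
round(mean_low_velocity_pct(curve), 1)
#> [1] 2.8
```

The recovered stasis equals the programmed dwell fraction (95% of the
cycle) to one frame quantum; the cycle-averaged low-velocity volume
reflects the pocket size.

Cohort-level analysis runs the same machinery over a seeded three-group
cohort (13 web / 7 atherosclerosis / 6 normal by default):

```r
result <- run_pipeline(cohort_spec(seed = 42),
                       pipeline_config(wall_metrics = FALSE))
result$sweep$best_threshold   # low-velocity threshold with max ROC AUC
#> [1] 3
result$tables$stasis_pct      # group means, Kruskal-Wallis, Dunn pairwise
```

Windkessel boundary conditions from vitals:

```r
rcr <- estimate_total_rcr(map = mean_arterial_pressure(126.9, 73.6),
                          mean_flow = 6, stroke_volume = 70,
                          pulse_pressure = 53.3)
distribute_outlets(rcr, outlet_diameters = c(0.5, 0.4))
```

See `vignettes/bulbflow-methods.Rmd` for the full model description,
parameter defaults, meshing regimes, and limitations.

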