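---
title: "Methods: hemodynamic stasis biomarkers in the carotid bulb"
author: "bulbflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemodynamic stasis biomarkers in the carotid bulb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulbflow)
```

## The problem

Shelf-like webs in the internal carotid artery (ICA) bulb are associated
with cryptogenic stroke in younger patients. The mechanistic hypothesis is
hemodynamic: a web promotes flow separation and a persistent slow
recirculation pocket downstream, and slow, oscillatory near-wall flow is
exactly the regime in which the coagulation cascade activates (Virchow's
stasis arm). `bulbflow` quantifies that regime from time-resolved 3D
velocity fields on tetrahedral meshes of the carotid bifurcation:

* **wall metrics** — wall shear stress (WSS), time-averaged WSS, wall shear
  rate $\gamma = |\tau|/\mu$ with the coagulation-linked low-shear
  threshold of 10 s$^{-1}$, the oscillatory shear index
  $\mathrm{OSI} = \tfrac12\left(1 - \|\int\tau\,dt\| / \int\|\tau\|\,dt\right)
  \in [0, 0.5]$, and the relative residence time
  $\mathrm{RRT} = 1/((1-2\,\mathrm{OSI})\,\mathrm{TAWSS})$;
* **volumetric metrics** — the percentage of the bulb region of interest
  (ROI) occupied by blood slower than a threshold (default 3 cm/s), per
  cardiac frame and cycle-averaged, and **stasis**, the percentage of the
  cycle during which such a region is present at all;
* **boundary conditions** — subject-specific three-element (RCR)
  Windkessel outlets: total resistance from mean arterial pressure over
  mean flow, capacitance from stroke volume over pulse pressure, split
  across outlets by Murray's law with exponent 2.1, validated by a 0D
  pressure-response integration;
* **cohort statistics** — pooled-percentile thresholds, ROC/AUC/Gini
  threshold-sensitivity analysis, and Kruskal–Wallis tests with Dunn
  pairwise follow-up.

Because no patient data ship with the package, every stage is validated
against a synthetic generator with *analytic* ground truth.

## Units

Everything internal is CGS: cm, s, g, dyn. Blood is Newtonian with
$\mu = 0.04$ Poise and $\rho = 1.06$ g/cm$^3$. Pressures cross the API in
mmHg and are converted with 1 mmHg = 1333.22 dyn/cm$^2$; resistances are
dyn·s·cm$^{-5}$, capacitances cm$^5$·dyn$^{-1}$.

## The synthetic generator

`make_tube_mesh()` and `make_bifurcation_mesh()` build structured
generalized-cylinder tetrahedral meshes: each axial station carries a
triangulated disk (center node plus concentric rings), disk triangles are
extruded to prisms and split into three tetrahedra. The idealized
bifurcation is a straight common carotid (CCA) trunk whose ICA and ECA
branches start internally tangent to the trunk circle and diverge at half
the branch angle each; the constructed flow-divider apex (where the branch
cross-sections become disjoint) is stored in the mesh metadata. A web is a
Gaussian focal reduction of the ICA radius profile
($R(s) = R_{\mathrm{ICA}}(1 - f\,e^{-((s-s_0)/w)^2})$), so a narrowing
fraction $f$ yields an ECST-style percent narrowing of $100f$ by
construction.

`sample_parabolic_field()` prescribes fully developed parabolic
(Poiseuille) flow, $v(r,t) = 2 Q_b(t)/(\pi R^2)\,(1-(r/R)^2)$ along the
local branch axis, with branch flows split by Murray fractions
($d^{2.1}$). This is not a Navier–Stokes solution; it trades physical
realism at the junction for *exact oracles*: flux, wall shear
($4\mu Q/(\pi R^3)$), and the low-velocity area fraction
($v_t/2\bar v$ for threshold $v_t \le 2\bar v$) are known in closed form.

`add_recirculation_pocket()` stamps a kinematic pocket into a sphere:
during a programmable *dwell fraction* of the cycle (the lowest-flow
frames) the pocket carries a rotation-like swirl at 80–100% of
`dwell_scale * peak_speed` (default cap 2.8 cm/s, i.e. strictly below the
3 cm/s working threshold); during the remaining frames it is flushed by a
uniform axial jet at `flush_factor * peak_speed` (default 11.2 cm/s, above
every sweep candidate), with the swirl sense reversed so near-pocket wall
shear alternates direction. The speed band is deliberate: a solid-body
swirl with a slow core would leak pocket volume into every lower
threshold, whereas the band makes the pocket invisible below its cap and
fully visible above it, so ROC separation in the threshold sweep peaks
uniquely at 3 cm/s. The dwell fraction is the ground truth that
`stasis_pct()` must recover.

### Two meshing regimes, on purpose

No-slip walls put a thin slow layer on every lumen: arbitrarily close to
the wall the speed is arbitrarily small. How a discrete low-velocity
metric sees that layer is a pure resolution question:

* **Resolved regime** (`boundary_layers = 3`, the `make_tube_mesh()`
  default): geometrically graded near-wall layers resolve the sublayer, and
  the discrete low-velocity fraction converges to the analytic
  $v_t/2\bar v$. This regime backs the closed-form oracles (the 5%
  fraction at $\bar v = 30$ cm/s, threshold 3 cm/s, accurate to ±0.5 at
  the default resolution and improving under refinement).
* **Unresolved regime** (`coarse_wall_fraction = 0.25`, the cohort
  default): a dense core resolves interior pockets while a single coarse
  wall layer leaves the sublayer unresolved, so the wall-adjacent cells'
  mean speeds stay above the threshold and the *pocket is the only
  low-velocity source*. Voxel-based thresholding of clinical-resolution
  data lives in this regime too — a control subject can only show 58%
  stasis if the metric does not see the viscous sublayer, which would put
  every subject at 100% stasis at any resolution that resolves it.

The cohort's inlet conditions keep the unresolved regime honest with a
margin: mean inlet velocity 24 ± 2 cm/s (flow = velocity × inlet area, so
flow scales with vessel size), systolic peak factor 1.9 (diastolic flow
~78% of mean, the high-diastolic character of carotid inflow), which keeps
the slowest wall-adjacent cell means above 3 cm/s throughout diastole for
every subject in the truncation range.

## The synthetic cohort

`make_cohort()` draws three groups (defaults 13 web / 7 atherosclerosis /
6 normal). Vitals are truncated normals around the study-population group
means (systolic/diastolic pressure, heart rate; stroke volume 70 ± 10 mL;
CCA inlet area 0.3 ± 0.05 cm$^2$). Web subjects get a 30 ± 11% web,
atherosclerosis subjects a 42 ± 17% narrowing, normal subjects neither.
All groups receive a bulb pocket whose dwell fraction and volume fraction
carry the group effect:

| group | dwell (latent) | pocket volume fraction |
|---|---|---|
| web | N(1.02, 0.05), clipped to [0, 1] | N(0.118, 0.030) |
| atherosclerosis | N(0.58, 0.10) | N(0.052, 0.020) |
| normal | N(0.84, 0.035) | N(0.050, 0.020) |

The web group's latent dwell mean sits above the ceiling so that most web
subjects (typically 9–12 of 13) dwell through 100% of the cycle, matching
the observed preponderance of full-cycle stasis in web patients, while the
clipped mean lands near 95–99%. Group means mirror the reported group
structure *directionally*; the SDs are deliberately tighter than the
reported between-subject SDs. That is a power calibration, not a
measurement claim: with groups of 13/7/6 the largest attainable
caw-vs-normal Dunn p is 0.0117, so reproducing pairwise significance in
≥90% of seeds — the package's stated cohort property — requires
near-complete group separation, which observed-size SDs (10–12 points of
stasis) cannot deliver. Passing cohorts therefore demonstrate that the
pipeline *recovers programmed effects and their ordering*, not that
real cohorts of this size would replicate significance at that rate.

The pocket's volume fraction floor (4% of the ROI) keeps every pocket
large relative to the mesh cells; the measured cycle-averaged low-velocity
volume is attenuated roughly twofold relative to the programmed fraction
because boundary cells straddling the pocket sphere average pocket and
bulk speeds. Group ordering is preserved (the attenuation is common), and
the recovered *stasis* is exact to one frame quantum because it is a
presence count, not a volume.

## Geometry

`extract_centerline()` marches cross-section centroids: planes advance
along the running tangent in steps of a quarter local radius; the section
in a thin slab is estimated from the tetrahedra it cuts, each contributing
its volume scaled by the overlapped fraction of its axial extent (and with
its axial coordinate collapsed to the overlap midpoint, which keeps the
estimate smooth when cells are larger than the slab). The equivalent
radius is $\sqrt{A/\pi}$. A deterministic 2-means split test (clusters
separated by more than the sum of their equivalent radii) detects the
bifurcation; past it the march follows the component heading toward the
requested outlet. The march terminates on crossing an outlet plane (the
final station is projected onto it), on stalled advance, or on an empty
slab. A 3-point running median removes single-station spikes (the split
transient); the trailing station is dropped if its radius collapses
(outlet edge effect). On analytic test geometries the extracted arclength
is within ~1% (straight and 90°-bent tubes) and the radius within ~1%;
compact webs (0.15 cm) are smeared by the slab width, under-reporting
ECST narrowing by about 5 points — the analytic-profile path of
`percent_narrowing()` carries the exact contract.

The bulb ROI runs from the narrowest lumen point (or the bifurcation, in
unnarrowed geometries) to 1.5 CCA diameters downstream along the
trunk→ICA path; membership is by projected arclength of face/cell
centroids with a transverse gate of 1.3 local radii to exclude the ECA.
The CCA diameter is twice the median local radius over the first 0.5 cm of
centerline. ROIs extending past the mesh record a truncation flag rather
than failing.

## Wall shear estimation

`compute_wss()` probes the interpolated velocity along each wall face's
inward normal at depth $\delta = 0.1 \times$ local radius. The default
estimator samples $\delta/2$ and $\delta$ and combines them one-sidedly to
second order, $\tau = \mu\,(4 v_t(\delta/2) - v_t(\delta))/\delta$, which
is exact for quadratic near-wall profiles; on the default tube mesh the
Poiseuille WSS error is ~1% and shrinks under refinement. The plain
single-probe variant (`method = "single"`) is retained for comparison and
carries the textbook first-order bias $\delta/(2R) = 5\%$ on Poiseuille
flow — which is why it is not the default: it would consume the entire
accuracy budget before interpolation error is even counted. Probe points
that cannot be located in the lumen flag the face invalid and drop it from
area statistics. Time averages over the uniform frames use the periodic
trapezoidal rule (equal to the frame mean). OSI's 0/0 case (identically
zero shear) is defined as 0.

The synthetic cohort's pockets are interior by design (one coarse layer
off the wall), so its wall metrics are near-degenerate — low-shear areas
~0, pooled top-1% OSI near 0 — and no group effect is programmed into
them; the estimators themselves are validated by the Poiseuille,
rectified-cosine and biased-sinusoid oracles instead.

## Statistics

ROC curves sweep unique score cutoffs; AUC uses the Mann–Whitney identity
with ties counted one half (the trapezoid of the curve agrees to
1e-12), and Gini = 2·AUC − 1 exactly. The threshold sweep scores subjects
by cycle-averaged low-velocity volume at each candidate
(0.5–10 cm/s) and returns the AUC maximizer, smallest candidate on ties.
Kruskal–Wallis uses `stats::kruskal.test` (tie-corrected H, chi-square
omnibus p; the approximation is cross-checked against a permutation oracle
at moderate group sizes); pairwise follow-up is Dunn's z on pooled ranks,
unadjusted by default (Bonferroni available) — the per-pair p < 0.05
reading matches how the source tables report pairwise values. Pooled
percentile thresholds (top-1% OSI, lowest-1% shear) pool face values
unweighted by area, with linear interpolation between order statistics
(type-7); an area-weighted variant exists but is non-default.

## Numerical choices and edge cases

* Strict inequalities everywhere a threshold is applied (`< γ`, `> OSI`,
  `< v_t`); boundary equality is measure-zero on continuous fields and
  excluded on discrete ones.
* Cell speed = mean of the four vertex speeds (one value per
  tetrahedron); sub-cell interpolation was rejected to keep the volume
  metric monotone in the threshold.
* Stasis presence floor: 0.1% of ROI volume by default (a literal > 0
  rule is mesh-noise-sensitive); 0 restores the literal rule.
* Dwell frames: nearest-integer rounding of `dwell_fraction * n_frames`
  with ties toward more frames; dwell is assigned to the lowest-flow
  frames.
* The 0D Windkessel response integrates
  $C\,dP_d/dt = Q(t) - (P_d - P_{ref})/R_d$ by classical RK4
  (via `deSolve`) from $P_d(0) = P_{ref} + R_d\bar Q$ over 5 cycles;
  steady state matches $P = P_{ref} + Q(R_p + R_d)$ to 0.1%.
* Proximal resistance fraction defaults to 0.09 (conventional carotid
  choice; the split is not identifiable from MAP and mean flow alone) and
  the venous reference pressure to 0 mmHg.
* Mesh resolutions used by the shipped tests: tubes at 24×28×9
  (axial × circumferential × radial, with 3 graded wall layers, ~34k
  tetrahedra), cohort bifurcations at ~31k tetrahedra with 36 axial ICA
  layers; these sizes were fixed by a convergence study against the
  analytic oracles (volume −0.8%, flux −1.5%, WSS ~0.8%, low-velocity
  fraction +0.18 at default, all improving under one refinement step).

## Known limitations

* Parabolic fields are not solutions of the Navier–Stokes equations in a
  bifurcation; junction flow, secondary flow and web-induced jets are not
  modeled. Passing tests show the *metrics* are correct, not that the
  generator reproduces real carotid hemodynamics.
* The pooled thresholds that are patient-data-dependent in the source
  study (top-1% OSI = 0.38, lowest-1% shear = 8.11 s$^{-1}$) cannot be
  reproduced synthetically; only the pooling mechanism is implemented and
  tested.
* Wall-metric group differences (low-shear and high-OSI areas) are not
  programmed into the synthetic cohort; its pockets are interior.
* Centerline extraction assumes a near-tubular lumen; it is a
  cross-section-centroid march, not a Voronoi medial axis, and smears
  sub-slab features (compact webs).
* Rigid walls, Newtonian rheology, no turbulence (bulb Reynolds numbers
  sit in the laminar 100–350 range by construction).
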