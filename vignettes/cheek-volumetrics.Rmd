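---
title: "Region-based volumetric measurement of midface soft-tissue response to maxillary repositioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based volumetric measurement of midface soft-tissue response to maxillary repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cheekmorph)
```

## The measurement problem

Patients with a skeletal Class III pattern and midface deficiency often show
a flat or concave anteromedial cheek. Le Fort I osteotomy corrects this by
advancing the maxilla (millimetres, anteriorly) and rotating it clockwise in
pitch (degrees, posterior impaction, steepening the occlusal plane). The
clinical questions this package addresses are quantitative: *how much does
the cheek soft tissue follow the underlying bone*, and *how much advancement
is needed for the cheek prominence to reach a normal position*?

Point-to-point landmark measurements answer these questions poorly because
no single soft-tissue point corresponds reliably across scans. The approach
implemented here is region based: the anteromedial cheek is delimited by
four anatomically fixed planes, and the average anteroposterior movement of
the whole region is measured as

$$ m \;=\; \frac{\Delta V}{A_{\mathrm{pre}}}, $$

the signed volume enclosed between the registered pre- and post-operative
surfaces inside the region (mm³), divided by the pre-operative surface area
of the region (mm²). The same measurement applied to the bone and the skin
yields a soft-to-hard tissue movement ratio per cheek side, and a
two-predictor linear model predicts the soft-tissue movement from the two
surgical parameters.

## Coordinate frame and reference planes

All geometry is expressed in a craniofacial frame built from landmarks that
surgery does not move:

* the **Frankfort horizontal plane (FH)** is fitted through both porions
  and the midpoint of the two orbitale points; its normal, oriented so that
  nasion is superior to basion, is the vertical axis;
* the **midsagittal plane (MSP)** is perpendicular to FH and contains sella
  and nasion; the anterior axis is the sella-to-nasion direction projected
  onto FH;
* the lateral axis completes a right-handed frame (positive toward the
  patient's right), with origin at sella.

FH is constructed from exactly the three stated constraints (two porions
and the orbitale midpoint) rather than a four-point least-squares fit,
because the plane definition names exactly those entities; with four
constraints the plane would no longer contain the porions exactly and the
incidence invariants used for validation would only hold approximately.

From the frame and landmarks, `construct_planes()` builds the full plane
set. The cheek region of interest (ROI) of each side is the intersection of
four half-spaces: lateral of the alare parasagittal plane (MCP), medial of
the exocanthion parasagittal plane (LCP), superior of the subnasale
horizontal plane (ICP), and inferior of FH. FH itself is the superior
bound because no other superior reference plane exists in the scheme. The
dentition defines the **occlusal plane** through the upper-incisor midpoint
and the midpoint of the two first-molar cusp points; the maxillary
rotational angle is the inclination of its trace in the midsagittal
projection, reported as a magnitude in [0°, 90°], with the direction of a
surgical change carried by the sign of the post-minus-pre difference
(clockwise positive). The upper-incisor landmark is stored directly as the
midpoint of the two central incisor tips, and the molar entry as one cusp
point per side; where cusp conventions are ambiguous the midpoint of the
two sided points is used. Note that cephalometric software often measures
occlusal-plane inclination against other references (e.g. sella–nasion);
such conventions yield systematically different angle values, so only
changes computed under the same FH-based definition are comparable with
this package's rotation output.

## Registration and its quality gate

Post-operative models are superimposed on the pre-operative models by a
best-fit rigid registration restricted to non-operated regions: vertices
strictly superior to FH plus vertices within 15 mm of nasion or either
exocanthion that are not inferior to FH (forehead and orbital areas). The
fit is iterative closest point with point-to-nearest-surface-point
correspondences (mesh resolutions differ between scans, so vertex-to-vertex
pairing would bias the fit), initialised deterministically by a Procrustes
fit of the non-operated landmarks (porion, orbitale, nasion, exocanthion).
Iterations stop when the RMS improves by less than 10⁻⁴ mm or after 100
iterations. The registration transform estimated on the bone is applied to
the bone and soft-tissue models and the landmarks alike.

Accuracy is certified by the RMS deviation over the same masked region,
with the conventional threshold of 0.5 mm (boundary inclusive). A patient
failing the gate is flagged and excluded from cohort statistics rather than
aborting a run. The same mask is used for fitting and for the RMS check;
both the mask margin and the threshold are configurable (`run_config()`).

## Volumetric subtraction

`clip_mesh_to_roi()` cuts a surface to the ROI, splitting boundary-crossing
triangles exactly at the planes and keeping only anterior-facing triangles.
`volumetric_change()` then samples the pre-operative patch and the
registered post-operative surface as anterior height fields $y(x, z)$ on a
regular grid over the patch's lateral-vertical footprint (ray casting along
the anterior axis, outermost hit) and integrates the height difference
times the cell area.

Design notes on this estimator:

* A height-field integral was chosen over boolean solid subtraction
  because the inputs are open surfaces, not watertight solids; an
  independent voxel-counting oracle (0.2 mm voxels) guards its correctness
  in the test suite (agreement within 2 % on curved patches).
* The default grid spacing is **0.4 mm**, matching the voxel size of the
  CBCT scans such surface models typically derive from; the cell size is
  adjusted per axis so an integer number of cells tiles the footprint
  exactly, which makes the flat-patch case exact (a planar patch translated
  by $d$ measures $m = d$ to machine precision).
* $\Delta V$ is signed (anterior positive). For a curved region a pure
  anterior translation by $d$ yields $m \le d$, because the surface area in
  the denominator exceeds the projected footprint; with the shallow
  curvature of a cheek ROI this bias is below 1 %.
* Rays missing the post-operative surface in more than 1 % of footprint
  cells abort the measurement ("surface coverage insufficient").

Bone advancement values are stratified for reporting into 1–2, 2–3, 3–4 and
>4 mm levels. The bins are half-open and left-closed ([1,2), [2,3), [3,4),
[4,∞)); shared endpoints must be assigned deterministically and the
left-closed rule keeps a value like 2.0 mm in the 2–3 mm level. Values
below 1 mm are flagged `below-range` rather than silently pooled.

## Cheek-mass position

The cheek-mass point (Ck) is the most anterior point of the cheek contour
on the mid-pupillary plane (the parasagittal plane through the cornea
point), searched in the vertical window between the subnasale level and the
orbitale level — the infraorbital region. "Most prominent/most convex" is
operationalised as maximal anterior coordinate on that profile, which is
what a horizontal-distance measurement against a coronal reference plane
responds to. The reported position is the signed anteroposterior distance
from Ck to the **cornea perpendicular plane** (coronal plane through the
cornea point): positive ahead of the cornea, negative behind it. Negative
values are deliberately admitted — a deficient cheek lies behind the cornea
perpendicular line, and the metric must express that.

The normative comparison uses a published healthy-norm summary for this
metric (mean 2.145 mm, SD 1.201 mm, n = 60, healthy Taiwanese Chinese
adults with normal occlusion); the constants are configurable in
`run_config()`. Because only summary statistics of the norm are available,
the comparison is a Welch two-sample t-test from summaries. Whether the
norm's effective sample size should be 60 individuals or 120 cheek sides is
not derivable from the published summary; 60 is used, and the resulting
p-values should be read with that ambiguity in mind (the group-minus-norm
differences themselves do not depend on it).

## Cohort statistics

* **Soft-to-bone ratio.** Per-side ratio of soft movement to bone
  advancement, summarised per side and pooled.
* **Side comparison.** Two-sided Welch t-test of right against left
  per-patient values.
* **Prediction model.** Least squares of the soft movement $Y$ on
  advancement $X_1$ and rotation $X_2$ *without intercept*:
  $Y = b_1 X_1 + b_2 X_2$. The zero intercept encodes the physical
  constraint that zero bone movement produces zero soft-tissue movement,
  and matches the form in which such predictive equations are reported.
  A configuration flag allows an intercept for sensitivity analysis.
* **R² convention.** For a no-intercept fit the uncentred sum-of-squares
  R² is inflated and not comparable with conventional reports, so the
  package defines R² as the squared Pearson correlation between observed
  and fitted response. This keeps the multiple correlation coefficient
  equal to `sqrt(R²)` and consistent with observed-versus-fitted scatter
  plots. Partial R² per predictor is the squared partial correlation of
  the response with that predictor given the other.
* **Correlation strength labels.** |r| < 0.3 weak, [0.3, 0.6) moderate,
  [0.6, 0.8] strong, > 0.8 extremely strong. The wording "larger than 0.8"
  forces 0.8 itself into the *strong* bin.
* **Reliability.** ICC for absolute agreement under a two-way
  random-effects ANOVA, single measures (ICC(2,1)), from the standard
  mean-squares decomposition.
* **Normality.** One-sample Kolmogorov–Smirnov statistic against a normal
  with the sample mean and SD, asymptotic p-value.
* **Multiplicity.** No multiple-testing correction is applied; the tables
  report raw two-sided p-values.

## The synthetic phantom

Because clinical CBCT-derived models cannot be redistributed, the package
ships a parametric craniofacial phantom (`make_phantom()`) that emulates
the *measurement situation*, not facial anatomy: a smooth anterior-facing
midface sheet (quadratic height field) with one shallow Gaussian cheek
prominence per side, a soft-tissue surface offset 8 mm anteriorly from the
bone, and the full landmark set placed consistently (porions/orbitale on
FH, sella/nasion on MSP, exocanthion/alare/subnasale bounding the ROIs,
cornea points on the mid-pupillary planes through the prominences,
dentition giving an 8° pre-operative occlusal inclination).

`apply_surgery()` moves the maxillary segment (inferior to FH, anterior to
the coronal plane through sella) rigidly — clockwise pitch about the
lateral axis through the upper-incisor point, then anterior translation —
and displaces the soft-tissue ROI anteriorly by the linear response
$a_1 d + a_2 \theta$ plus coherent per-side noise, at full amplitude across
the ROI and tapering to zero over a 6 mm band outside it. Key choices:

* **Shallow prominence (1.5 mm, σ = 12 mm).** Keeps the ROI surface area
  within ~1 % of its projected footprint so that the volumetric movement
  estimator is essentially unbiased on the phantom and parameter-recovery
  tests can use tight tolerances. Real cheeks are more curved; on real
  data the estimator inherits the (documented, downward) area bias.
* **Coherent noise, not per-vertex noise.** Soft tissue deforms smoothly;
  white per-vertex noise would average out of $\Delta V / A$ almost
  entirely and make the response variance uncontrollable. Each side gets a
  single zero-mean Gaussian amplitude.
* **Two sides share the surgical parameters** and differ only in noise,
  which mirrors how left/right summaries of a real cohort are nearly
  identical.

`generate_cohort()` simulates a cohort of 48 patients / 96 sides (the
default study conditions): advancements drawn uniformly within the four
strata at proportions 14/34/34/14 per 96 sides (the open-ended stratum is
sampled on [4, 5.5] mm), rotation from a Normal(3.341°, 2.346²) truncated
at zero (clockwise semantics), response coefficients a₁ = 0.627 mm/mm and
a₂ = 0.070 mm/deg, and noise calibrated analytically so the population R²
equals 0.788:

$$ \sigma^2_\varepsilon \;=\; \mathrm{Var}(a_1 X_1 + a_2 X_2)\,
   \frac{1 - R^2}{R^2}, $$

with the predictor variances computed exactly from the stratified-uniform
and truncated-normal generative distributions (`calibrate_noise_sd()`).
The *fast* mode draws outcomes directly from this response model; the
*mesh* mode builds one phantom per cohort and measures every patient
through the full geometric pipeline. At zero noise the two modes agree on
the soft response within 0.1 mm per record. In mesh mode the measured bone
movement additionally contains the rotation's geometric contribution at
ROI height (the rotation centre is at the incisors, below the ROI), as it
would in real measurements.

```{r cohort-example}
tab <- generate_cohort(cohort_spec(seed = 1), mode = "fast")
fit_prediction_model(tab, region = "Total")
```

## Numerical choices and problem sizes

* Phantom mesh resolution 2 mm (about 5,500 triangles per surface),
  volumetric grid 0.4 mm, ICP capped at 100 iterations with a 10⁻⁴ mm
  improvement threshold and at most 1,000 mask vertices: with these sizes
  a full patient measurement takes well under a second, and the
  reproduction experiments (20-seed regression recovery; 20-phantom ratio
  recovery; 96-phantom bone-movement recovery) finish in seconds to a few
  minutes on one CPU. These sizes are the package defaults and the ones
  the tests and `scripts/acceptance.R` state and use.
* Plane and frame constructions carry 10⁻⁶-grade incidence tolerances;
  orthonormality is enforced to 10⁻⁹.
* Triangles crossing ROI boundaries are split exactly at the planes;
  vertices lying exactly on a profile plane are included in the cheek
  profile (a mesh line can coincide with the mid-pupillary plane).
* All RNG consumption is order-deterministic given a seed (truncated
  normals are drawn by inverse CDF, never rejection), so cohorts and
  reports are byte-reproducible.

## What passing tests do and do not show

The phantom validates the *machinery*: plane construction, registration
and its QC gate, clipping, the volumetric estimator against analytic and
voxel oracles, the cheek metric against brute-force scans, and recovery of
known generative parameters through the full pipeline. It does not
validate anatomical realism — there is no nose, no eye socket, no mandible,
no scanner noise, and soft tissue responds by a prescribed linear field
rather than mechanics. Consequently, agreement on the phantom says the
implementation measures what it defines; it cannot certify accuracy on
clinical scans, where segmentation quality, registration mask choice and
true tissue mechanics dominate.

Other known limitations: the registration is rigid only (adequate for the
non-operated fitting region, by construction); the height-field estimator
requires the ROI surface to be a single-valued anterior graph, which holds
for cheeks but not for arbitrary regions; and the normative comparison
inherits the published summary's sample-size ambiguity noted above.
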