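# cheekmorph

Region-based 3D volumetric analysis of the anteromedial cheek soft-tissue
response to Le Fort I maxillary advancement and clockwise (pitch) rotation.

Orthognathic surgery for skeletal Class III patients with midface
deficiency moves the osteotomised maxilla forward (advancement, mm) and
rotates it clockwise (posterior impaction, degrees). Surgeons and
orthodontists need to know how much the overlying cheek soft tissue
follows the bone, and how much advancement is needed for the cheek
prominence to reach a normal position. `cheekmorph` implements the full
measurement chain for pre/post 3D surface models (CBCT-derived bone and
skin meshes, STL/PLY) and the associated prediction statistics, plus a
synthetic craniofacial phantom so every stage can be exercised and
validated without clinical data.

## Method

For each cheek side, a region of interest is bounded by four anatomically
fixed planes (parasagittal planes through exocanthion and alare, the
horizontal plane through subnasale, and the Frankfort horizontal plane).
After best-fit rigid superimposition of the post-operative model on the
pre-operative model over non-operated regions (certified by RMS deviation
≤ 0.5 mm), the average sagittal movement of the region is

    m = ΔV / A_pre        [mm]

where ΔV (mm³) is the signed volume between the registered surfaces inside
the ROI and A_pre (mm²) the pre-operative surface area of the ROI. Applied
to bone and skin this yields per-side soft-to-hard movement ratios, and the
soft response is predicted from the two surgical movements by the
zero-intercept model

    Y = b1·X1 + b2·X2

with Y the cheek soft-tissue sagittal movement (mm), X1 the maxillary
advancement (mm) and X2 the rotation (degrees); R² is reported as the
squared correlation between observed and fitted Y, with partial R² per
predictor. The cheek-mass position (the most anterior contour point on the
mid-pupillary plane below the orbit, signed against the cornea
perpendicular plane) is compared per advancement stratum against published
healthy normative values (2.145 ± 1.201 mm, n = 60) by Welch t-tests from
summary statistics.

## Worked example

Simulate one patient — a phantom given a 3 mm advancement and 2° clockwise
rotation with the default soft-tissue response (0.627 mm/mm,
0.070 mm/deg) — and measure it end to end:

```r
library(cheekmorph)

ph   <- make_phantom()
post <- apply_surgery(ph, surgery_params(advancement = 3, rotation = 2))
run_patient(ph, post)
#> <patient_result> RMS 0.000 mm (QC pass), rotation change +2.00 deg
#>   side tissue delta_volume pre_area movement
#> 1    L   bone     2398.978 655.0570 3.662243
#> 2    L   soft     1311.180 655.0570 2.001627
#> 3    R   bone     2398.980 655.0564 3.662250
#> 4    R   soft     1311.180 655.0564 2.001629
```

The registration is exact (the phantom's forehead/orbital mask region is
untouched by surgery), the occlusal-plane change recovers the applied 2°,
and the measured soft movement matches the prescribed response
(0.627·3 + 0.070·2 = 2.02 mm). The bone ROI moves more than the 3 mm
translation because the clockwise rotation (centred at the incisors, below
the ROI) adds its own anterior displacement at cheek height — as it does in
real patients.

Cohort-level statistics on a simulated 96-side cohort:

```r
tab <- generate_cohort(cohort_spec(seed = 1), mode = "fast")
rep <- run_cohort(tab)
rep$ratios
#>   region  n  mean    sd
#> 1      R 48 0.698 0.118
#> 2      L 48 0.748 0.143
#> 3  Total 96 0.723 0.133
rep$models[, c("region", "b1", "b2", "r_squared", "r")]
#>   region    b1     b2 r_squared     r
#> 1      R 0.596 0.0811     0.838 0.915
#> 2      L 0.639 0.0809     0.823 0.907
#> 3  Total 0.618 0.0810     0.822 0.906
```

The pooled soft-to-bone ratio (~0.72) and the fitted coefficients scatter
around the generative values, and the stratified cheek-mass comparison
(`rep$norm_comparison`) shows small-advancement strata significantly below
the healthy norm while the 3–4 mm and >4 mm strata are not.

A thin command-line front end over these functions is installed at
`inst/scripts/cheekpipe.R` (`simulate`, `measure`, `cohort` subcommands,
STL/PLY meshes and JSON/CSV landmark and cohort files).

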