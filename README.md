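# hydroffr

Hydrostatic pressure correction of invasive coronary pressure indices
(FFR and resting Pd/Pa), with 3D-centerline height extraction, per-segment
correction tables over the Syntax nomenclature, and cutoff
reclassification analysis.

## The problem

FFR is the ratio of distal coronary to aortic pressure, Pd/Pa, under
maximal hyperemia; the resting Pd/Pa is the same ratio without hyperemia.
Both are compared against dichotomous treatment cutoffs (FFR ≤ 0.80,
resting Pd/Pa ≤ 0.92). The pressures are equalized at the catheter tip in
the coronary orifice, but the wire sensor is then advanced distally — in a
supine patient, typically several centimetres **above** the orifice in the
LAD or **below** it in the CX. The blood column in between adds a
hydrostatic pressure

```
p_h = f · d,          f = ρ_blood / ρ_mercury = 1.05 / 13.55 ≈ 0.077 mmHg/mm,
d   = y_orifice − y_sensor  (mm, negative when the sensor is higher)
```

to the distal reading, so the artifact-free quantities are

```
Pd_corr    = Pd − p_h
index_corr = index_meas − p_h / Pa       (Δ = p_h / Pa, ∝ 1/Pa)
```

In the distal LAD (d ≈ −57 mm) the measured FFR reads about 0.044 *low*
at Pa = 100 mmHg; in the distal CX (d ≈ +28 mm) about 0.022 *high* —
enough to flip a borderline call. This package computes `d` from 3D
coronary centerlines (directly, via the foreshortening-corrected chord
triangle, or from a 2D lateral projection), applies the correction,
tabulates the mean effect per Syntax epicardial segment, and counts
cutoff reclassifications over a cohort. A synthetic cohort generator with
known ground truth supports end-to-end validation. For clinical audiences:
this is a research tool, not a medical device.

## Worked example

Correct a small lesion table (shipped with the package; heights in mm,
pressures in mmHg):

```r
library(hydroffr)
f <- system.file("extdata", "synthetic_lesions_example.csv", package = "hydroffr")
res <- run_pipeline(f, pipeline_config())
res$lesions[, c("lesion_id","segment","ffr_measured","ffr_corrected","ffr_reclassified")]
#>   lesion_id  segment ffr_measured ffr_corrected ffr_reclassified
#> 1      L001 LAD_dist    0.8000000     0.8437360             TRUE
#> 2      L002  LAD_mid    0.8000000     0.8373653             TRUE
#> 3      L003  CX_dist    0.8095238     0.7889905             TRUE
#> 4      L004 RCA_dist    0.8100000     0.7961400             TRUE
#> 5      L005       PL    0.8000000     0.7745900            FALSE
res$report
#> Reclassification after hydrostatic correction (n = 5 lesions)
#>   FFR   (cutoff 0.80): 4 reclassified (80%)
#>   Pd/Pa (cutoff 0.92): 2 reclassified (40%)
```

L001 sits exactly on the cutoff (positive) but its sensor is 56.8 mm above
the orifice, so the corrected FFR 0.844 is clearly negative — a
reclassification. L005 (PL, sensor below the orifice) corrects downward,
from borderline-positive to clearly positive: same side, no flip.

The per-segment correction table at reference conditions (Pa 100 mmHg,
measured FFR 0.80, measured Pd/Pa 0.92):

```r
tab <- build_correction_table(reference_heights())
data.frame(segment = tab$segment,
           p_h   = round_half_out(tab$p_h_mean_mmhg, 3),
           ffr   = round_half_out(tab$ffr_at_ref, 3),
           pdpa  = round_half_out(tab$pdpa_at_ref, 3),
           delta = round_half_out(tab$delta, 3))
#>     segment    p_h   ffr  pdpa  delta
#> 1      none  0.000 0.800 0.920  0.000
#> 2  LAD_prox -1.054 0.811 0.931 -0.011
#> 3   LAD_mid -3.552 0.836 0.956 -0.036
#> 4  LAD_dist -4.374 0.844 0.964 -0.044
#> 5   CX_prox  1.153 0.788 0.908  0.012
#> 6   CX_dist  2.159 0.778 0.898  0.022
#> 7  RCA_prox -0.492 0.805 0.925 -0.005
#> 8   RCA_mid -0.528 0.805 0.925 -0.005
#> 9  RCA_dist  1.382 0.786 0.906  0.014
#> 10       PL  2.283 0.777 0.897  0.023
#> 11       PD  1.350 0.787 0.907  0.014
```

Reading row `LAD_dist`: the mean distal-LAD sensor height of −56.80 mm
corresponds to −4.374 mmHg of hydrostatic pressure, so a measured FFR of
0.80 there is really 0.844 (and a measured Pd/Pa of 0.92 really 0.964) —
a Δ of −0.044 at Pa = 100 mmHg.

Synthetic cohorts and geometry:

```r
coh <- generate_cohort(cohort_spec(seed = 7), outdir = "cohort7")  # lesions.csv, centerlines/, truth.json
cl  <- coh$centerlines[["L001"]]
height_direct(cl)                      # signed orifice-minus-sensor height
d <- derive_triangle_inputs(cl)        # chord, foreshortening, alpha
height_triangle(d$inputs, d$distal_is_anterior)  # identical height
compare_height_methods(coh$centerlines, noise_sd_mm = 2)  # 2D-vs-3D Pearson r
```

See `vignette("hydrostatic-correction")` for the model, conventions
(coordinate frame, sign and rounding rules, boundary handling) and
limitations, and `inst/cli/hydroffr.R` for a command-line front end
(`correct`, `table`, `simulate`, `geometry`, `compare`).

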