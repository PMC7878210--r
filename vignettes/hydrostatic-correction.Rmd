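---
title: "Hydrostatic pressure correction of intracoronary pressure indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrostatic pressure correction of intracoronary pressure indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroffr)
```

## The physical problem

Fractional flow reserve (FFR) and the resting Pd/Pa ratio compare the
pressure at the wire sensor, distal to a stenosis, against the aortic
pressure measured at the catheter tip in the coronary orifice, where the
two transducers were equalized. With the patient supine, the sensor rarely
sits at the orifice's height: the LAD climbs toward the anterior chest
wall, so its sensor sits several centimetres *above* the orifice, while the
CX runs posteriorly *below* it. The intervening blood column contributes a
hydrostatic pressure

\[ p_h = f \cdot d, \qquad d = y_\text{orifice} - y_\text{sensor}, \]

where \(d\) is the signed height difference in mm (negative when the
sensor is above the orifice) and \(f\) is the mmHg read per mm of blood
column. By Pascal's law \(f\) is the ratio of the specific gravities of
blood and mercury, \(1.05 / 13.55 = 0.0775\), conventionally rounded to
\(f = 0.077\) mmHg/mm (`conversion_factor()`). The artifact-free distal
pressure and indices are then

\[ P_d^\text{corr} = P_d - p_h, \qquad
   \text{index}^\text{corr} = \text{index}^\text{meas} - p_h / P_a . \]

A sensor above the orifice reads low (negative \(p_h\)), so LAD indices
correct upward; a sensor below reads high, so CX indices correct downward.
The shift \(\Delta = p_h / P_a\) is a fixed pressure divided by the aortic
pressure — inversely proportional to \(P_a\), hence relatively larger in
hypotensive patients. Near the dichotomous treatment cutoffs (FFR
\(\le 0.80\), resting Pd/Pa \(\le 0.92\)) a shift of 0.01–0.04 routinely
changes the clinical call, which is what `reclassification_report()`
quantifies.

## Height extraction from 3D centerlines

A `centerline()` is an ordered 3D polyline in mm from orifice to sensor,
in a fixed patient frame: x right→left, y posterior→anterior (the vertical
axis in supine position), z caudal→cranial. The frame itself is a package
convention — chosen so that the lateral X-ray view (LAO 90°, cranial 0°)
projects along x and shows the height axis horizontally, without
foreshortening — since only the lateral-view behaviour is anchored in
angiographic practice. Three extraction routes are provided and are exact
duals of one another on noise-free geometry:

* **Direct** (`height_direct()`): \(d = y_\text{first} - y_\text{last}\).
  This is the ground truth the other two must reproduce.
* **Triangle** (`height_triangle()`): the in-view chord length is inflated
  back to its true 3D length by the view's foreshortening fraction,
  \(c = c_\text{view} / (1 - F)\) with
  \(F = 1 - c_\text{view}/c\) (`foreshortening()`), and the height is the
  vertical leg of the right triangle with hypotenuse \(c\):
  \(b = c \cos\alpha\). We define \(\alpha\) as the **3D** angle between
  the orifice→sensor chord and the vertical axis oriented toward the
  distal side, so \(\alpha \in [0, 90]\), \(b \ge 0\), and a separate
  `distal_is_anterior` flag fixes the sign (anterior sensor ⇒ negative
  height). An in-projection reading of \(\alpha\) would make the identity
  only approximate; the 3D reading makes
  `height_triangle(derive_triangle_inputs(cl)) == height_direct(cl)` exact
  (to 1e-9 mm in the property tests), which is why we adopt it.
  `height_triangle()` itself accepts \(\alpha \in [0, 180]\) with a signed
  \(b\), for callers supplying their own convention.
* **2D lateral** (`height_2d_lateral()`): the horizontal screen-coordinate
  difference in the lateral projection, which equals the direct height
  exactly because that projection preserves y. Optional Gaussian noise
  (`noise_sd_mm`) emulates manual 2D quantitation error.

Foreshortening is defined on the **chord**, not the arc, because the
triangle construction corrects the chord; the arc enters only through the
tortuosity diagnostic `arc_chord_ratio()` (\(\ge 1\), 1 iff straight).
Chords shorter than 1e-6 mm and views in which the chord is fully
foreshortened (\(F = 1\)) raise errors rather than returning 0/NaN: both
are unmeasurable configurations, and silent zeros would corrupt cohort
statistics downstream.

## The per-segment correction table

`build_correction_table()` evaluates the correction at reference
conditions — \(P_a = 100\) mmHg, measured FFR 0.80, measured Pd/Pa
0.92 — for the mean height of each of the ten Syntax epicardial segments
(proximal/mid/distal LAD, proximal/distal CX, proximal/mid/distal RCA, PL,
PD; left main and sub-2 mm branches are excluded because pressure wires are
not parked there). `reference_heights()` carries the per-segment mean ± SD
heights observed in a 305-measurement supine cohort; these are inputs, not
estimates made by this package.

```{r table}
tab <- build_correction_table(reference_heights())
data.frame(segment = tab$segment,
           p_h = round_half_out(tab$p_h_mean_mmhg, 3),
           ffr = round_half_out(tab$ffr_at_ref, 3),
           pdpa = round_half_out(tab$pdpa_at_ref, 3),
           delta = round_half_out(tab$delta, 3))
```

Numerical conventions worth stating explicitly:

* Display rounding is **half-away-from-zero** at 3 decimals
  (`round_half_out()`), not R's round-half-even.
* The tabulated \(\Delta\) is defined as the *displayed* (3 dp) mean
  hydrostatic pressure divided by \(P_a\). For nine segments this is
  indistinguishable from the unrounded ratio; for the PD row it is not
  (1.350/100 = 0.0135 → 0.014, while the unrounded 0.013498 would print
  0.013), and the two-stage definition is the one consistent with the
  printed pressure column. Per-lesion corrections (`correct_index()`)
  are never rounded internally.
* The ± column for the hydrostatic pressure is reported as
  \(f \cdot \text{SD}(d)\), a scaling approximation: the source cohort's
  printed ± values are not exactly reproducible this way for every
  segment, and no per-lesion products are available to recompute them, so
  the column is descriptive only and never asserted in tests.
* The FFR and Pd/Pa columns of any table row differ by exactly
  \(0.92 - 0.80 = 0.12\), and negating a height mean negates \(p_h\) and
  \(\Delta\) — both are invariants in the test suite.

The PL/PD rows assume a right-dominant circulation (their origin in the
reference cohort); `reference_heights("left_dominant")` relabels the
origin as CX but carries the same numbers, because no left-dominant
reference statistics exist — a documented limitation, not a claim.

## Classification and reclassification

`interpret_index()` calls an index **positive** (hemodynamically
significant) when it is at or below its cutoff; the boundary value counts
as positive, matching the clinical reading of "FFR ≤ 0.80". The source
data do not state their boundary convention, so ours is declared and
configurable (`boundary_positive = FALSE` for strict inequality). A lesion
is *reclassified* when its measured and corrected values straddle the
cutoff; `reclassification_report()` reports counts and integer-percent
rates. The clinical cohort rates (12% for FFR, 27% for Pd/Pa) depend on
the original patient-level data and are context, not a target: on
synthetic cohorts the rates vary with the seed.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions so that the entire
pipeline is testable without patient data:

* 41 lesions split 3/18/6 across proximal/mid/distal LAD, 1/5 across
  proximal/distal CX and 2/6 across mid/distal RCA — the clinical cohort's
  mix.
* True FFR ~ truncated normal(0.83, 0.04) on [0.70, 0.90] (the study's
  inclusion window); true resting Pd/Pa ~ truncated normal(0.90, 0.04)
  constrained above the lesion's FFR and at most 1; \(P_a\) ~ normal(100,
  10) floored at 60 mmHg. Means and SDs are the cohort's descriptive
  statistics; the normal/truncated-normal *forms* are our modelling
  choice, as the source reports moments only.
* Heights ~ normal(mean, SD) per segment from `reference_heights()`
  (untruncated, again a declared choice), realized as smooth parametric
  centerlines whose vertical coordinate follows a smoothstep ramp — so the
  generated height is exact to construction tolerance (1e-6 mm) — with
  per-segment x/z drifts and bows reflecting the qualitative vessel
  courses (LAD anterior toward the apex, CX posterior-downward, RCA
  rightward then caudal into PL/PD). The bows guarantee arc > chord and a
  nonzero lateral-view foreshortening of the chord.
* Pressures are generated at beat-mean granularity by the forward model
  \(P_d = (\text{index}_\text{true} + p_h/P_a) P_a + \varepsilon\),
  \(\varepsilon \sim N(0, \texttt{noise\_sd\_mmhg})\), for rest and
  hyperemia independently. The default noise is 0 so that correction
  recovers the truth to 1e-12 (the round-trip contract); the noisy
  validation property uses 1 mmHg. No waveform morphology, stenosis
  flow-pressure law, drift, whip or wedge artifacts are modelled — all
  target quantities are beat-mean ratios, so white beat-mean noise is the
  appropriate granularity.
* Lesions are independent (the 37-patients/41-lesions clustering of the
  clinical cohort is ignored; all its analyses are per-lesion), and one
  seeded RNG drives every draw, recorded in the `truth.json` manifest.

What passing tests on this generator do show: the geometry, correction
algebra, aggregation and classification are internally consistent and
invert the forward model exactly. What they cannot show: fidelity of the
correction on real angiographic reconstructions, whose height errors are
not white noise (calibration, frame selection and point-picking errors are
structured), nor the clinical reclassification rates, which depend on how
close real lesions sit to the cutoffs.

## Problem sizes and tolerances used in validation

The test suite uses 1000 random centerlines for the triangle/direct
equivalence (tolerance 1e-9 mm), 500 heights per segment for parameter
recovery (3 standard errors), 300 centerlines with 2 mm 2D noise for the
method correlation (r > 0.95 expected; noise-free agreement is exact), and
the standard 41-lesion cohort elsewhere — sizes at which every Monte Carlo
bound has comfortable margin while the whole suite runs in seconds.
Unrounded table cells are compared at ±0.0005, i.e. half a display unit.

## Known limitations

* Blood density is fixed at 1.05 g/cm³ by default; hematocrit varies it by
  a few percent (pass `rho_blood` to `conversion_factor()` to explore).
* Centerlines are assumed end-diastolic; cardiac motion between frames is
  out of scope, as is any image processing (DICOM ingestion, vessel
  segmentation, two-view reconstruction, calibration).
* Phasic (systolic/diastolic) pressure structure, and therefore iFR, is
  not modelled.
* The per-segment table is an empirical average; per-lesion correction
  from an actual measured height is always preferable when available.
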