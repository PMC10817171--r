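# myoqt1

Quantitative T1 (qT1) measurement of the uterine myometrium from
variable-flip-angle (VFA) MRI, with manual and semiautomatic ROI
placement and a full inter/intra-rater reproducibility battery.

## The problem

Native T1 of the myometrium is a candidate quantitative biomarker, but a
mean-qT1 measurement is only as reproducible as the region of interest it
is averaged over. When two readers trace the uterus by hand, the mean qT1
they report can differ by several percent simply because their contours
pick up different amounts of endometrium, bowel, bladder and vessels.
This package implements two ROI protocols over the same T1-mapping
pipeline so their reproducibility can be compared quantitatively:

- **Manual**: the myometrial mask is the traced whole-uterus polygon minus
  the traced endometrial polygon (junctional zone included).
- **Semiautomatic**: the reader supplies only an endometrial-center click
  and a rough external myometrial contour. The algorithm grows the
  endometrial ROI from the seed by an adaptive intensity tolerance
  (starting at ±3% of the seed intensity, widened in 1% steps while the
  region stays clear of the contour), samples the band between the
  endometrial ROI and the contour, keeps band pixels within ±1.96 SD of
  the band mean as the myometrial ROI, registers that ROI onto the SPGR
  image by exhaustively minimizing the within-ROI sum of squared
  deviations over integer translations in {−10..+10}², and averages the
  T1 map over the optimally placed ROI. No active contours, no
  randomness: the pipeline is fully deterministic.

## The model

T1 maps come from the standard two-point VFA solution of the spoiled
gradient echo (SPGR) steady state. With

```
S = M0 · sin(α_eff) · (1 − E1) / (1 − E1 · cos(α_eff)),
E1 = exp(−TR/T1),  α_eff = B1 · α_nominal
```

the coordinates `y = S/sin(α_eff)`, `x = S/tan(α_eff)` of the two
flip-angle acquisitions (4° and 18°, TR ≈ 5 ms) lie on a line of slope
`m = E1`, so `T1 = −TR / ln m`. A B1 scale map corrects flip-angle
inhomogeneity; slopes outside (0, 1) and T1 outside (1, 10000] ms are
marked invalid rather than clipped. ROIs are defined on an inversion
recovery image (TI = 200 ms, magnitude signal `M0·|1 − 2·exp(−TI/T1)|`),
which maximizes endometrium/myometrium contrast.

Agreement statistics follow the usual repeatability battery: per-subject
CoV and pairwise error `|a−b|/((a+b)/2)·100%`, average-measures two-way
random-effects absolute-agreement ICC(2,k) with F-based 95% CI,
Bland–Altman bias and limits of agreement with a proportional-bias
correlation test, Wilcoxon signed-rank and paired t comparisons.

Everything is testable without patient data through a digital uterus
phantom: an elliptical myometrial ring around a brighter endometrial
core, with bladder/bowel/vessel confounders, per-tissue T1/M0, Gaussian
acquisition noise, a smooth B1 field, and an optional integer IR-to-SPGR
misregistration.

## Worked example

```r
library(myoqt1)

spec <- phantom_spec(noise_sd = 0.8, b1_range = c(0.95, 1.05),
                     ir_to_spgr_shift = c(3, -2))
truth   <- make_phantom(spec)
ir      <- simulate_ir(truth, ti = 200, seed = 1)
spgr_lo <- simulate_spgr(truth, fa_deg = 4,  tr = 5, seed = 2)
spgr_hi <- simulate_spgr(truth, fa_deg = 18, tr = 5, seed = 3)

# the B1 map travels with the SPGR acquisition (shifted frame)
b1 <- apply_shift(image2d(truth$b1_map), 3, -2, fill = 1)$pixels
t1map <- compute_t1_map(spgr_lo, spgr_hi, b1 = b1)
#> compute_t1_map: 18/16384 pixels invalid (0.1%)

semiauto_qt1(ir, spgr_hi, t1map, seed = c(64, 55),
             contour_poly = ellipse_polygon(c(63.5, 55), c(30, 22), 0.3))
#> <semiauto_result> tolerance 9%, endo 555 px, myo 1358 px, shift (3, -2), mean qT1 1514.0 ms
```

The region grower settled at a 9% tolerance, the SD filter kept 1358
myometrial pixels, the registration search recovered the simulated
(3, −2) px misregistration exactly, and the mean qT1 of 1514 ms sits
0.9% from the 1500 ms ground truth (the residual is the second-order
noise bias of the VFA fit at 2% noise). The manual protocol on the same
slice, which has no shift correction, is pulled down by background
pixels:

```r
mean_qt1(manual_myometrial_mask(ellipse_polygon(c(63.5, 55), c(30, 22), 0.3),
                                ellipse_polygon(c(63.5, 55), c(16, 11), 0.3),
                                dim(ir$pixels)), t1map)
#> manual mean qT1: 1409.6 ms
```

The full observer study on 23 phantom subjects with jittered contours:

```r
replicate_study(n = 23, seed = 7)
#> <replicate_report> n = 23 phantom subjects, seed 7
#> interobserver:
#> <method_comparison>
#>   manual:        mean CoV 2.11%, mean error 2.98%
#>   semiautomatic: mean CoV 0.05%, mean error 0.07%
#>   Wilcoxon p (CoV) = 2.384e-07, p (error) = 2.384e-07
#> intraobserver:
#> <method_comparison>
#>   manual:        mean CoV 2.43%, mean error 3.44%
#>   semiautomatic: mean CoV 0.05%, mean error 0.07%
#>   Wilcoxon p (CoV) = 2.384e-07, p (error) = 2.384e-07
```

Semiautomatic placement is dramatically less sensitive to tracing
variation than manual placement — the direction the method was designed
to achieve.

## Command line

A thin CLI wraps the same functions (installed under `exec/myoqt1`, or
call `run_cli()` directly):

```sh
myoqt1 phantom --out study/ --seed 5 --shift-dx 2 --shift-dy -1
myoqt1 t1map --spgr-lo study/spgr_fa04.dcm --spgr-hi study/spgr_fa18.dcm --out study/t1map
myoqt1 segment-semiauto --ir study/ir.dcm --spgr study/spgr_fa18.dcm \
       --t1map study/t1map.dcm --roi rois.json --out study/semi.json
myoqt1 agreement --table1 observers.csv --out report.json
myoqt1 replicate --n 23 --seed 7 --out replicate.json
```

DICOM I/O is a minimal single-frame explicit-VR-little-endian codec
(written for the phantom round trip; not a general DICOM reader). ROI
coordinates come from JSON files (0-based, x = column, y = row);
measurement tables from csv/tsv/xlsx.

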