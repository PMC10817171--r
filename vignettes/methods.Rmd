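---
title: "Methods: myometrial qT1 measurement and its reproducibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: myometrial qT1 measurement and its reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoqt1)
```

## Scope and model

`myoqt1` measures the mean quantitative T1 of the uterine myometrium on a
single oblique pelvic slice and quantifies how reproducible that
measurement is across readers and sessions. Three model components carry
all of the science; everything else is plumbing.

**VFA T1 estimation.** Two spoiled gradient echo acquisitions at nominal
flip angles 4° and 18° (TR ≈ 5 ms) are combined pixel-wise through the
linearised SPGR equation: with $y_i = S_i/\sin\alpha_i$ and
$x_i = S_i/\tan\alpha_i$ (effective angles $\alpha_i = B_1\alpha_{nom,i}$),
the slope $m = (y_2-y_1)/(x_2-x_1)$ estimates $E_1 = e^{-TR/T_1}$ and
$T_1 = -TR/\ln m$. The estimate is exact on noiseless model signals (the
package tests this to $10^{-6}$ relative on phantoms, including spatially
varying B1). Assumptions: ideal spoiling, steady state, a long-TR
magnitude IR model ($S = M_0\,|1-2e^{-TI/T_1}|$) for the anatomical
reference image only — IR is never used to fit T1.

**ROI protocols.** The manual protocol rasterizes two traced polygons
(whole uterus, endometrium) and subtracts them. The semiautomatic
protocol needs only a seed click and a rough external contour; it grows
the endometrial region from the seed with an adaptive relative-intensity
tolerance, samples the band between the grown region and the contour,
extracts the myometrial ROI as the band pixels within ±1.96 SD of the
band mean, and registers that ROI from the IR frame onto the SPGR frame
by exhaustive integer-translation search minimizing the within-ROI sum
of squared deviations (SSD).

**Agreement battery.** Per-subject CoV ($SD/mean \times 100$, sample SD)
and pairwise error ($|a-b|/\overline{ab} \times 100$, identically
$\sqrt2\,\times$ CoV for pairs), average-measures two-way random-effects
absolute-agreement ICC — ICC(2,k) $= (MS_R - MS_E)/(MS_R + (MS_C -
MS_E)/n)$ — with the F-based confidence interval of McGraw & Wong
(single-measures interval with Satterthwaite degrees of freedom, stepped
up by Spearman–Brown), Bland–Altman bias and 1.96-SD limits of
agreement with a difference-vs-mean Pearson test for proportional bias,
and Wilcoxon signed-rank / paired-t method comparisons.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| flip angles | 4, 18 | deg | standard low/high VFA pair; the low angle anchors the PD end, the high angle the T1 end of the line |
| TR | 5 | ms | clinical 3D-SPGR range is 5.0–5.6 ms; each image carries its own TR and the fit errors if the pair disagrees by >1% |
| TI (reference image) | 200 | ms | near-maximal endometrium/myometrium magnitude contrast for the tissue T1s involved |
| T1 validity window | (1, 10000] | ms | fits outside are discarded (`NA`), never clipped, so ROI means are not silently biased |
| initial growth tolerance | 3 | % of seed intensity | threshold half-width at which region growing starts |
| tolerance increment / cap | 1 / 100 | % | widened until the grown region would touch the contour |
| SD filter width | 1.96 | sample SDs | retains ≈95% of a Gaussian band; drops flow voids and partial-volume pixels |
| registration search | ±10 | px | covers clinically seen IR-to-SPGR misregistration; exhaustive, so the global optimum is guaranteed |
| phantom tissue T1s | 1500 / 2200 / 300 | ms | myometrium / endometrium / background; myometrium centred in the observed in-vivo 1200–2500 ms range |
| phantom noise | 0.8 (= 2% of the low-FA myometrial signal) | signal units | high-but-realistic SNR for segmented tissue |
| contour jitter (observer model) | 2 | px SD per vertex | emulates tracing variation between readers |

## Design decisions in genuinely open places

- **Seed intensity reference.** "The endometrial intensity determined by
  the user" is read as the IR intensity at the clicked pixel; a 3×3-mean
  option (`seed_stat = "mean3x3"`) exists for noisy data. The tolerance
  is relative to this fixed seed intensity, not to the evolving region
  mean, keeping the grower monotone in the tolerance and deterministic.
- **Connectivity.** 8-connectivity for region growing and contour loops
  (one-pixel rasterized contours stay closed under it); the
  enclosed-region flood runs 4-connected so it cannot slip diagonally
  through an 8-connected contour.
- **SSD reference mean.** The deviation at each candidate shift is taken
  about that shifted ROI's *own* mean on the SPGR image (within-ROI
  variance), i.e. the registration seeks the most homogeneous placement.
  The alternative — a fixed mean from the unshifted ROI — is implemented
  behind `mean_mode = "fixed"`. Ties are broken by smallest shift
  magnitude, then row-major order, making (0, 0) win on constant images.
- **Registration target.** The high-flip-angle (18°) SPGR is the default
  SSD target: it carries the stronger T1 weighting and hence the better
  myometrium/surroundings contrast. Selectable per call.
- **Out-of-bounds shifts** are excluded from the search rather than
  renormalized; phantom anatomy is kept ≥11 px from the borders so the
  full ±10 window is always admissible.
- **ICC model.** "Average ICC" is implemented as ICC(2,k) (two-way
  random, absolute agreement, average measures — the SPSS reliability
  default for this design); ICC(3,k) is available behind a flag. Point
  estimates are oracle-tested against `aov()` mean squares, and both
  models were cross-checked against an independent implementation
  (pingouin) during development.
- **Difference orientation** in Bland–Altman is observer 1 − observer 2
  (or first − second session); swapping columns flips the bias sign, a
  tested invariant.
- **Wilcoxon policy.** Zero differences are dropped; the exact null
  distribution is used for ≤25 untied non-zero differences, otherwise
  the normal approximation with continuity correction.
- **Expert visual confirmation** of the registered ROI is replaced by
  machine-readable QC (the recovered shift, the full 21×21 SSD surface
  and its flatness) — there is no human in the loop.

## What the phantom emulates — and what it does not

The digital phantom provides an elliptical myometrial ring around a
brighter endometrial core, extra-uterine confounders (urine-filled
bladder with long T1, bowel with short T1, a small vessel), per-tissue
T1/M0, additive Gaussian noise, a smooth radial B1 field and an integer
IR-to-SPGR translation. The replicate study draws per-subject anatomy
and myometrial T1 (truncated normal around 1500 ms), simulates three ROI
input sets per subject (two observers, one repeat) by jittering contour
vertices and the seed click, and runs both pipelines.

It does **not** emulate: Rician magnitude noise (Gaussian is used since
segmented-tissue SNR is high; the simulators take the noise model as a
parameter in units of signal SD), partial-volume voxels or texture
within tissues, junctional-zone contrast distinct from outer myometrium,
slice-profile or echo-train effects, motion, or 3D anatomy. A green
phantom test therefore establishes algorithmic correctness and relative
robustness of the two protocols under tracing variation — not clinical
performance. In particular the phantom's sharp tissue boundaries make
the semiautomatic method look *more* dominant than the published in-vivo
comparison, where both methods faced real texture; the package asserts
only the direction of the difference, never its in-vivo magnitude.

## Numerical notes

- **VFA noise bias.** $T_1 = -TR/\ln m$ is nonlinear in the signals, so
  averaging many noisy per-pixel fits leaves a second-order bias
  ($\propto \sigma^2$): measured ≈ +12 ms at 2% noise, ≈ +0.4 ms at
  0.25% noise on a 13 000-pixel ring. The mean-recovery property is
  therefore asserted within 3 SE at 0.25% noise and within 1% of truth
  at the working 2% noise level.
- **Degenerate inputs.** Equal linearisation abscissae ($x_2 = x_1$),
  non-positive slopes and out-of-window T1 all yield `NA`; ROI means
  exclude `NA` pixels and report the exclusion count; an all-invalid ROI
  is an error. Constant images: min–max windowing emits all zeros with a
  warning; SSD surfaces become constant and the tie-break returns (0, 0);
  Bland–Altman reports an undefined proportional bias with a warning.
- **Rasterization** uses the pixel-center even-odd rule (0-based
  coordinates, x = column, y = row, y downward) everywhere; the manual
  mask area identity $|whole \setminus endo| = |whole| - |whole \cap
  endo|$ is exact.
- **Determinism.** Segmentation contains no randomness; simulators take
  explicit seeds and restore the caller's RNG state; repeated
  `replicate` runs with the same arguments are byte-identical.

## Known limitations

- The DICOM codec is a minimal explicit-VR-little-endian single-frame
  subset sufficient for the package's own round trip; real scanner files
  with other transfer syntaxes are rejected, not guessed at.
- Non-integer pixel data is quantized to 16 bits on DICOM write (with a
  warning); the analysis path works on in-memory doubles, so this only
  affects the file-based CLI route (≈0.06 ms quantization step for a
  0–4000 ms T1 map).
- Reproduction of the published agreement statistics requires the
  study's per-subject supplementary tables, which cannot be shipped with
  the package; the corresponding acceptance tests fail with an
  explanatory message rather than being skipped, and every statistic
  they would compute is oracle-tested on synthetic tables instead.
- B1 acquisition is out of scope: a B1 map is consumed (phantom-supplied
  or file-based), never measured.
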