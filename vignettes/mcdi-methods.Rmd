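---
title: "Multichannel computed diffusion images: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multichannel computed diffusion images: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5, fig.height = 4)
library(mcdi)
```

## The problem and the model

Prostate diffusion MRI is read from two coupled images: a high-b-value
DWI (tumor bright) and the ADC map (tumor dark). Discordant pairs — bright
on both (T2 shine-through) or dark on both (blackout) — are the reason
neither image may be read alone. The mcDI approach replaces the
side-by-side read with a single grayscale image whose intensity is a
function of the *pair* of values at each voxel.

### Diffusion math

All signal modelling is mono-exponential:

$$S(b) = S_0 \, e^{-b \cdot \mathrm{ADC}},$$

with $b$ in s/mm² and ADC in mm²/s. The package stores ADC on the 12-bit
scanner scale, 1 unit $= 10^{-6}$ mm²/s with ceiling 4095 $(= 2^{12}-1)$.
The two-point estimate from a $b_0/b_{800}$ acquisition is

$$\mathrm{ADC} = \frac{\ln\!\big(S(b_\mathrm{low})/S(b_\mathrm{high})\big)}{b_\mathrm{high}-b_\mathrm{low}},$$

clipped to $[0, 4095]$; voxels with a non-positive signal at either
b-value get ADC 0 rather than an error, because air and background voxels
are ubiquitous and the fusion stage must not crash on them. The computed
high-b image (default $b = 1500$ s/mm²) is the forward extrapolation
$S(b_t) = S(b_\mathrm{ref})\,e^{-\mathrm{ADC}(b_t-b_\mathrm{ref})}$.

### The unit-square coordinate

Each voxel is mapped to $(a, d) \in [0,1]^2$:

* $a = \mathrm{ADC}/4095$ — normalization by the *potential* maximum of the
  storage scale, so $a$ is comparable across patients;
* $d = S(b_{1500}) / \max S$ — normalization by the per-patient global
  maximum over **all** b-value volumes and slices. In vivo that maximum is
  urine in the bladder at $b=0$; the phantom reproduces this property. An
  optional robust-quantile divisor is available for hot-pixel resilience
  but is off by default.

### The intensity map

A map is a continuous function $[0,1]^2 \to [0,1]$:

$$\mathrm{blend}(a,d) = \frac{\cos t \cdot a + \sin t \cdot (1-d)}{\mathrm{span}},
\qquad
v(a,d) = \mathrm{clip}_{01}\!\Big[\mathrm{blend} + w\,\max\!\big(1-\tfrac{d}{\tau},0\big)\,(1-\mathrm{blend})\Big].$$

The main gradient runs from black at ADC 0 to white at ADC 1 (an ADC-like
reading, dark = suspicious); tilting it clockwise by $t$ degrees mixes in
the inverted DWI, so increasing DWI signal always lowers the gray value.
Below the **no-tumor zone** threshold $\tau$ the value is pushed toward
white with weight $w(1-d/\tau)$, which vanishes continuously at $d=\tau$:
background (fat, bone) with near-zero high-b signal is lightened without
touching any tissue a tumor voxel could occupy.

Parameters, defaults, and why:

| parameter | default | unit | rationale |
|---|---|---|---|
| `tau` | 0.05 | normalized DWI | empirical bound of the no-tumor zone: essentially no tumor voxel has normalized high-b DWI below it |
| `tilt_step` | 10 | degrees/level | reproduces the qualitative clockwise progression of the nine-map slider; a named parameter, not a constant |
| `suppression_step` | 1/8 | weight/level | linear ramp from $w=0$ (level 1) to $w=1$ (level 9) |
| `level` | 5 | 1–9 | the map most often chosen by readers; level 1 is exactly the original ADC image |

The published description never prints the tilt angles or suppression
weights of maps 2–9; the schedule above is this package's fixed, documented
choice, overridable per call.

### The span rescaling (a genuinely open design point)

The tilted projection $\cos t\cdot a + \sin t\cdot(1-d)$ must be rescaled so
each map's output spans exactly $[0,1]$ — display window and center are
fixed, so cross-level brightness must stay comparable. Over which region
should it span $[0,1]$? Two readings exist:

* **whole unit square** — divisor $\cos t + \sin t$;
* **operative region $d \ge \tau$** — divisor $\cos t + \sin t\,(1-\tau)$,
  on the grounds that the sub-$\tau$ strip is overridden by the suppression
  gradient and is not part of the gradient's readout.

The package uses the second whenever suppression is active (and the first
for $w = 0$, which keeps the pure-DWI limit, $t = 90°$, $w = 0$, exactly
$1-d$). The reason is a property the first reading quietly violates:
*background brightness must be non-decreasing in level*. With the
whole-square divisor, increasing the tilt darkens high-ADC background
(near $a \to 1$, $d \to \tau^-$) faster than the vanishing suppression can
lighten it, and continuity at $d=\tau$ pins the limit — the orderliness of
the nine-map slider breaks in that corner. With the operative-region
divisor one can show $\mathrm{blend} \ge a$ and
$\partial\,\mathrm{blend}/\partial t \propto (1-d) - (1-\tau)\,a > 0$
everywhere in the strip, so every stated property holds simultaneously:
level-1 identity, monotone in $a$ (non-decreasing) and in $d$
(non-increasing, $d\ge\tau$), exact $[0,1]$ span, continuity at $\tau$, and
level-ordering of the background. Sub-$\tau$ blends may exceed 1 before the
final clip; the clip is applied once, after the suppression term, which
preserves all monotonicities.

### Fusion and histograms

The mcDI is the reverse lookup $\mathrm{mcdi}(v) = \mathrm{value}(a_v, d_v)$ —
a pure per-voxel function, evaluated analytically (the map is rasterized
only for display, so the level-1 identity is exact rather than quantized to
1/256). Gray output stays floating point in $[0,1]$; 8-bit quantization
(round half up) happens only at PNG export.

Joint histograms use 256 bins per axis, bin $k$ covering
$[k/256, (k+1)/256)$ with the last bin closed so 1.0 is representable (the
standard convention; the method's description states no rule). Display
intensity is $I = \mathrm{int}(\ln A)$ with $A$ floored at 1; `int` is read
as truncation (= floor for $A \ge 1$) and isolated in one function,
`log_intensity()`. ADC indexes the x/first axis, DWI the y/second.

```{r map-plot, eval = FALSE}
autoplot(intensity_map(level = 5))
ph <- generate_phantom()
pair <- normalize_patient(ph$series)
autoplot(accumulate(pair, ph$mask, "pz"))
autoplot(fuse(pair, intensity_map(level = 5)))
```

## The synthetic phantom: what it emulates, and what it does not

`generate_phantom()` paints ellipsoidal compartments (painter's order:
later entries overwrite earlier ones) with ground-truth ADC and baseline
signal, simulates each b-value by the mono-exponential law, and optionally
adds magnitude Rician noise (the correct distribution for magnitude MR;
approximately Gaussian at high SNR). Defaults, chosen once for
diffusion-MRI plausibility (the source study publishes no tissue
statistics):

| compartment | label | ADC (10⁻⁶ mm²/s) | S0 | role |
|---|---|---|---|---|
| background | 0 | 300 | 80 | fat-suppressed tissue, dark at every b |
| peripheral zone | 2 | 1600 | 700 | normal PZ, fast decay at high b |
| transitional zone | 3 | 1200 | 600 | TZ |
| tumor | 1 | 700 | 1100 | restricted diffusion, bright at b1500 |
| bladder | 0 | 3000 | 2000 | fluid; dominates the series maximum at b=0 |

`generate_phantom()` is noise-free by default (determinism for exact
round-trip tests); `default_study()` draws a cohort with per-subject jitter
(±10% ADC, ±15% S0, ±2 voxels position, ±10% radii) and Rician noise
σ = 15, roughly SNR 45 in the PZ at b = 0.

What a green test on this phantom establishes: the math of the pipeline —
fit/extrapolation round trips, normalization conventions, histogram
conservation, monotone map behavior, and the qualitative separations the
method relies on (tumor at lower $a$, higher $d$ than PZ; almost no tumor
mass below $\tau$; level-5 tumor-vs-PZ contrast above the plain ADC's).
What it does **not** establish: reader-level diagnostic performance.
Ellipsoids have no partial-volume boundaries, no susceptibility or motion
artifacts, no T2 dependence (signal is fully determined by S0 and ADC), no
rectal gas distortions, and the published sensitivity/specificity and
agreement values are outputs of a human reader study that no simulation
reproduces.

## Reader statistics

`krippendorff_alpha()` implements the nominal-data coefficient
$\alpha = 1 - D_o/D_e$ via the coincidence matrix, with the pairable-values
rule for missing ratings (units with fewer than two ratings drop out). When
every pairable value is identical, $D_e = 0$ and $\alpha$ is reported as
`NA` (undefined), never coerced to 1. The test suite checks the
implementation against an independent pair-enumeration oracle, exhaustively
over all binary tables up to 5 units × 3 raters. The source study's tables
label these agreement numbers both "Krippendorff's alpha" and "kappa" in
different places; this package implements alpha and leaves kappa out.
Likewise out of scope, deliberately: McNemar's test, ANOVA, and Bonferroni
correction — off-the-shelf hypothesis tests peripheral to the imaging
method. `diagnostic_metrics()` reports the standard 2×2 ratios and flags
empty-denominator cells as undefined rather than zero.

## Numerical and I/O choices

* `cospi`/`sinpi` make the 0° and 90° limits exact, so "map 1 equals the
  ADC image" and "the 90° map equals $1-d$" hold with zero error.
* Voxel index order is (slice, row, column) everywhere; DICOM series are
  sorted by slice position along the normal (instance number as fallback),
  never by file name.
* NIfTI-1 is the native on-disk format (integer data bit-exact, doubles
  stored as float64); the DICOM reader supports the common part-10
  explicit-VR little-endian uncompressed case and rejects everything else
  with a format error. No NIfTI/DICOM R package exists in the target
  environment, so both codecs are minimal, purpose-built implementations
  (cross-checked against nibabel during development).
* Degenerate inputs: all-zero series → explicit degenerate-input error;
  empty mask selection → valid all-zero histogram; out-of-square
  coordinates (impossible by invariant) are clipped defensively before
  lookup.

## Known limitations

* The nine-map schedule (10°/level, $w$ linear) is a reconstruction of a
  qualitative description; the original angles are unpublished.
* Two figure captions in the source disagree on whether a "strict vertical"
  readout is the ADC or the DWI; the package follows the unambiguous
  statement that map 1 is the original ADC image and treats the captions as
  describing different geometric conventions. The worked example "voxel
  (0.3, 0.2) → 70% gray" specifies no map and is not used for calibration.
* Multi-point (>2 b-values) log-linear ADC fitting, IVIM/kurtosis models,
  noise-floor correction, registration/resampling, and DICOM writing are
  out of scope.
* Interactive map selection (the reading-workstation slider) is emulated by
  emitting all nine volumes; there is no GUI.
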