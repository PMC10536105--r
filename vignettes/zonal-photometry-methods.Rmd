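---
title: "Zonal ring photometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zonal ring photometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonephot)
```

## The measurement and its model

An ellipsoidal-reflector photometer places the sample at the first focus of
a truncated mirror ellipsoid and a CCD conjugate to the second. Unlike an
integrating sphere, which deliberately destroys spatial structure, the
ellipsoid maps scattering angle to image radius: the collimated beam lands
in a bright central circle, and light scattered at increasing angles fills
concentric rings. The analysis therefore reduces each frame to three zone
statistics around a radial symmetry point — the central circle A1 (radius
R1, nominally the collimated-beam image), the middle ring A2 (R1–R2) and
the external ring A3 (R2–R3). A zone's *illuminance* is the sum of its
pixel digital numbers (DN) divided by its pixel count: a mean gray level,
not a radiometric lux value.

For a scattering standard built by stacking polyethylene film layers, ring
illuminance varies with sample thickness $d$ (mm) and laser power $P$ (mW)
as

$$E_T(d) = m\,e^{n d} \qquad\text{(transmitted light, } d \gtrsim 0.7\text{ mm)},$$
$$E_R(d) = a\,\ln d + b \qquad\text{(reflected light)},$$

with each coefficient a polynomial in $P$: $m(P)$, $a(P)$, $b(P)$
quadratic, and $n(P)$ of degree 6. The transmitted law is the familiar
near-exponential extinction of forward-scattered light; the reflected
signal saturates slowly because backscatter builds up with the number of
scattering centers but is bounded by the finite albedo. The degree-6 form
for $n(P)$ is an empirical calibration shape, not a physical claim; with
ten power levels it has three residual degrees of freedom and its
reliability ($r^2$) is reported rather than assumed.

The fitted coefficient tables for both rings, together with their
published reliabilities, ship as `reference_power_polynomials()`; they
drive the synthetic generator and the validation suite.

## Stage by stage

### Region of interest and symmetry point

`detect_roi()` thresholds the frame at a fraction $\tau$ of its maximum DN
and takes the bounding box of the surviving pixels, scanning rows and
columns. The box is accepted when the *form objective function* — its
side ratio, rows/cols — lies within `form_limits`; otherwise $\tau$ is
lowered by `tau_step` and the scan repeated down to `tau_min`. Defaults
are $\tau_0 = 0.5$, step 0.05, floor 0.05 and form limits (0.8, 1.25):
the procedure is prescribed by the measurement protocol but the constants
are not, and these values accept mildly elliptical spots while rejecting
bar-like artifacts. An accepted box is expanded to a square about its own
center (clipped at frame edges) because the ring analysis expects a square
ROI while real bright areas are only near-square.

`symmetry_point()` implements the parity rule: an odd-sided ROI's
symmetry point is the center of its central pixel; an even-sided ROI's is
the corner shared by the four central pixels. Coordinates are 0-based
(row, col) with pixel centers at half-integers, so both cases are exact
in continuous coordinates.

### Zone masks and illuminance

Zone membership uses the Euclidean distance from each pixel's center to
the symmetry point with half-open intervals: A1 is $dist < R_1$, A2 is
$R_1 \le dist < R_2$, A3 is $R_2 \le dist < R_3$. Half-openness makes the
three zones an exact partition of the R3 disk — boundary pixels are never
counted twice and never dropped. Membership is all-or-nothing by pixel
center; subpixel area weighting would change zone areas (and hence every
published-scale illuminance) unpredictably, and "area" here is a pixel
count by definition. R2 and R3 are batch constants so ring illuminances
are comparable across a study; R1 defaults to the collimated-beam radius
in pixels (beam diameter 2 mm, scaled by the configured px/mm factor).

Reflected-light frames carry darkened rectangles where the delivery tube
and prism shadow the lens. These are *not* excluded by default — the
shadow is systematic, identical in every frame of a batch, so it shifts
ring levels without corrupting their thickness dependence. Exclusion via
`occlusion_spec()` is available for sensitivity analysis, and
`zone_illuminance()` removes excluded pixels from both the DN sum and the
area so an excluded pixel's value is provably irrelevant.

### Replicate averaging

Measurements repeat at three sites along the sample perimeter with three
captures each; `average_replicates()` takes the arithmetic mean of each
zone illuminance over all sites × captures per (thickness, power, mode)
condition. No outlier rejection is applied — the protocol specifies plain
averaging.

### Two-stage regression

Stage 1 fits the thickness law per (mode, ring, power). The reflected fit
is ordinary least squares of $E$ on $\ln d$ — a closed-form simple
regression, cross-checked in the tests against the analytic solution on
1,000 random instances. The exponential fit is linearized first
($\ln E$ on $d$) to get starting values, then refined by
Levenberg–Marquardt least squares on the *original* scale
(`minpack.lm::nlsLM`): pure log-linear fitting re-weights additive noise
toward thick, dim samples and would bias the amplitude. If refinement
fails or cannot improve (exactly degenerate data such as constant $E$,
where the gradient is singular), the log-linear solution is kept, so the
returned residual sum of squares never exceeds the starting fit's.
Thicknesses at or below `d_min` (default 0.7 mm) are excluded from
transmitted fits — below that the single-exponential law does not hold —
and the exclusion count is reported.

Stage 2 fits each coefficient family against power with unweighted least
squares at the fixed degrees (2 for m, a, b; 6 for n), via `lm()` on a raw
polynomial basis. On the ten-level power grid the raw Vandermonde system
is still well within double-precision comfort: noiseless recovery in the
tests is ~1e-14 absolute on the degree-6 coefficients. $r^2$ is
$1 - SS_{res}/SS_{tot}$ with centered $SS_{tot}$ throughout; a perfect
fit of constant data reports 1 rather than 0/0. Published reliability
values sit beside specific coefficients in the source table and their
assignment (amplitude fit vs rate fit) is ambiguous, so the package
reports one $r^2$ per polynomial and makes no claim about reproducing
that assignment.

## The synthetic generator

`render_frame()` draws a piecewise-constant spot: every pixel gets its
zone's target level (classified by the same half-open rule the analysis
uses), plus i.i.d. Gaussian read noise, optional multiplicative occlusion
rectangles, clipping to the DN range and rounding. The generator emulates
what the analysis *assumes*: flat zone levels, additive sensor noise,
quantization, a systematic occlusion shadow. It deliberately omits
speckle, optical blur, radial falloff within a zone, flat-field error and
saturation — so passing recovery tests demonstrate the pipeline's
correctness on its own model of the data, not robustness to every real
optical artifact. Within-zone flatness is harmless here because the
analysis consumes only zone means.

The CCD's noise model is unpublished; Gaussian read noise is an assumption
and its default magnitude (0 for recovery studies, a few DN when noise is
wanted) is a choice, not a measured property. `generate_study()`
enumerates thickness × power × mode × site × capture with the study's
actual conditions as defaults: ten powers 1.8–23.4 mW in 2.4 mW steps,
thicknesses 0.1–10 mm, 3 sites × 3 captures, 480×640 frames
(the sensor used is 640×480; the resolution is a default, not enforced).
Per-frame seeds derive deterministically from the base seed, so a study is
bit-reproducible.

One scale decision matters: the published illuminance magnitudes (m near
7,700 at mid power) exceed the 8-bit DN range, and the illuminance unit is
never stated. The generator therefore exposes a `gain` (DN per model
unit) and defaults to 16-bit frames. The regression operates on
illuminance values, so gain cancels when fitting gain-scaled data; results
in model units are recovered by dividing it out.

## Validation paths and problem sizes

Two end-to-end paths exist. The *model-level* path evaluates the forward
model into an illuminance table (`model_illuminance_table()`) and feeds
the regression directly; it is exact up to floating point and is what the
acceptance script and the coefficient-recovery tests use (transmitted
grid 0.8–10 mm step 0.2; reflected 0.1–10 mm step 0.1; both rings; ten
powers). The *image* path renders frames and measures them; rounding to
integer DN bounds each zone mean within half a DN of its target, i.e. a
relative floor around $10^{-5}$ at 16-bit depth, so image-path tests
assert at the quantization bound while model-path tests assert coefficient
recovery at $10^{-3}$ relative (quadratic families) and $10^{-9}$ absolute
(the degree-6 rate family, whose high-order terms are $10^{-6}$–$10^{-8}$
and where relative error is ill-conditioned — the same split
`compare_to_reference()` uses). Test problem sizes (96×96 to 240×200
frames, 50 random geometries, 100 random spot placements, 1,000 random
regression instances) were chosen as the smallest sizes that still
exercise every boundary case; the package itself has no size limits.

## Known limitations

* ROI size is data-driven. The nominal link between the ROI and the
  ellipsoid focal parameter (16.7 mm) requires an object-to-sensor
  magnification that is not published; the focal-parameter check is a
  config cross-reference only.
* The functional forms are fixed; no model selection or uncertainty
  intervals on coefficients are provided, and error models are
  homoscedastic.
* Occlusion rectangles are supplied, not detected; there is no flat-field,
  dark-frame or saturation handling.
* 16-bit PNG can be read but not written (the underlying writer is
  8-bit-only); 16-bit output uses TIFF or PGM.
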