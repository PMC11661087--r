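---
title: "Measuring axon caliber from membrane-labeled images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring axon caliber from membrane-labeled images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axoncaliber)
```

## The measurement model

A membrane-localized fluorophore labels only the plasma membrane of an
axon. In a single optical plane a tube of diameter $d$ therefore
appears as two bright boundary lines separated by $d$, each blurred by
the microscope's point-spread function. Along a scan perpendicular to
the center axis the expected intensity is the sum of two Gaussians,

$$I(x) = e^{-(x - d/2)^2 / 2\sigma^2} + e^{-(x + d/2)^2 / 2\sigma^2},$$

where $\sigma$ is the PSF standard deviation
($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$). Caliber is scored as the
distance between the two intensity peaks. Two properties of this model
drive the design:

* for $d \gg \sigma$ the peak separation equals $d$ up to a shift of
  order $e^{-d^2/2\sigma^2}$, which is negligible for $d \ge 0.3$ µm at
  $\sigma \approx 0.06$ µm;
* for $d < 2\sigma$ the two Gaussians merge into a single central
  maximum, so sufficiently thin axons are *unmeasurable*, not merely
  noisy. The pipeline flags these (`single_peak`) rather than reporting
  a number, and separately flags calibers below a configurable
  resolution limit (`below_resolution`, default 0.14 µm). Flagged
  values are excluded from means but still counted by the
  fraction-below-resolution exclusion rule, so datasets dominated by
  unresolvable segments are dropped as a whole rather than silently
  thinned.

`analytic_linescan_profile()` implements the closed form and serves as
the independent oracle for the measurement code: the renderer and the
measurement module are validated against it separately, never against
each other alone.

## Line-scan scoring

Profiles are sampled by bilinear interpolation at `center + offset ·
normal`, with the normal obtained from central differences on the
centerline polyline (one-sided at segment ends). Choices that matter:

* **Coordinates.** Continuous µm with the origin at the center of pixel
  (1,1); pixel centers at integer multiples of the pixel size. This
  makes the interpolation identity (sampling at pixel centers returns
  stored values) exact, which is tested.
* **Smoothing** (`smoothing_sd`, default one pixel). Bilinear
  interpolation yields piecewise-linear profiles whose kinks can split
  a peak into plateaus; a one-pixel Gaussian restores a smooth profile
  on which parabolic refinement is meaningful. Oracle tests disable it.
* **Peak selection.** Local maxima (plateau runs collapse to their
  central sample; runs touching the scan ends are ignored) must exceed
  a prominence of 10% of the profile range. The reported pair is the
  *nearest* qualifying peak on each side of offset zero, not the two
  global maxima — this is robust to a neighboring axon crossing the
  scan window, which instead raises the `ambiguous_peaks` flag when a
  second candidate on one side is within 10% of the chosen peak's
  height.
* **Sub-pixel refinement.** A three-point parabola around each peak,
  clamped to half a sample step. With default settings the noiseless
  recovery error across diameters 0.3–1.4 µm is of order $10^{-4}$ µm,
  far inside the 0.04 µm acceptance band.
* **Degenerate inputs.** A flat (zero-range) profile is an error; a
  scan leaving the image reports the clipped offsets; measurement
  positions inside the branch-point exclusion radius (3 µm by default,
  5 µm for symmetry analysis) are dropped, not errored.

## Branch architecture and taper

Segment caliber at a branch point is the mean of measurements 3, 4 and
5 µm from the branch point; any flagged position makes the segment
unusable. Roles: S1 is the thicker secondary, S2 the thinner; ties
break deterministically to the lower segment id and give symmetry 1.
Two identities are maintained exactly and tested to $10^{-12}$:
symmetry $= (S_2/P)/(S_1/P)$ and area ratio
$= (S_1/P)^2 + (S_2/P)^2$. Population summaries pool both $S/P$ ratios
from every branch point. Regressions are ordinary least squares via
`stats::lm`, with $R^2 = 1$ defined as 0 for a constant response.

## Dynamics

Summaries use the sample ($n-1$) standard deviation throughout — series
are short (a dozen frames), where the $n$ vs $n-1$ choice is material;
%RSD and fold range are scale-invariant by construction, which is
enforced by property tests. Below-resolution frames enter as missing
values: excluded from mean/SD, visible in `n_valid`. This mirrors the
caveat that dynamicity of the thinnest axons is, if anything,
underestimated. The four qualitative behaviors are *scripted* by the
generator, not classified from data: classification was qualitative in
the underlying experimental practice, and an automatic classifier would
test a model this package does not claim.

## Division geometry

The rounded apical surface is modeled as a circular arc with chord $c$
(the rounded planar extent) and sagitta $h$ (cell height):
$R = (c^2 + 4h^2)/8h$, $\mathrm{arc} = 2R \arcsin(c/2R)$, taking the
major arc when $h > c/2$ and the chord itself when $h = 0$. This is the
simplest two-parameter model consistent with orthogonal projections of
rounding cells; the flat-state path is the straight chord $\ell$, per
the assumption that the axon is anchored at the cell borders and runs
straight across the surface. The model enters only through
`arc_path_length()` so an alternative surface model can be swapped in.

Round/flat frames are the consecutive pair with the greatest
border-to-border length increase; ties (within a $10^{-9}$ relative
tolerance, which absorbs floating-point noise in scripted schedules)
resolve to the earliest pair. A sequence with no increase is an error —
no flattening was captured.

## The synthetic generator

The generator emulates the imaging regime the measurement was designed
for: membrane-only fluorescence (two boundary line sources, no lumen
signal, constant amplitude along the length), an isotropic Gaussian PSF
of 0.14 µm FWHM, 0.04 µm pixels, constant background, Poisson shot
noise and Gaussian read noise, and 5-minute frame intervals. Pixel size
and PSF are stated nowhere as properties of a specific instrument;
these defaults satisfy Nyquist sampling for an Airyscan-class lateral
resolution and are fully configurable. Defaults of 100 photons membrane
amplitude over a background of 10 give peak SNR near 10, the regime
used for the noise-robustness checks.

Rendering deposits analytic Gaussian spots along the boundary curves
(line integral discretized at $\sigma/3$), so a perpendicular cut
through a rendered straight tube equals the closed-form two-Gaussian
profile to within quadrature error (< 2% RMS, tested). Radius profiles
are Gaussian "pearls" on a constant base, with a sinusoidal preset for
subtle thick/thin stretches. Scripted behaviors: a traveling pearl
(center advances `speed` per frame), focal inflation/deflation
(triangular amplitude ramp over onset–offset), uniform segment
widening/narrowing, and a toggled negative-amplitude constriction.
Scenes are 2D; the division scenario's vertical dimension exists only
in the arc-length geometry model, matching how heights are estimated
from orthogonal projections rather than rendered pixels.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: deconvolution artifacts and
non-Gaussian PSF tails, intensity variation along the membrane,
out-of-focus light from tilted segments, photobleaching, stage drift,
and the second-channel texture of basal cells (only border positions
are modeled). Recovery results on synthetic tubes bound algorithmic
error, not total experimental error.

Determinism is a contract: a fixed seed yields bit-identical frames,
and every scene is written with its full ground truth (JSON sidecar)
so downstream quantities can be recomputed without the images.

## Statistics

The paired permutation test flips the sign of each pair difference;
the statistic is the mean difference (the simplest paired statistic,
matching the "significant drop" framing of paired comparisons). All
$2^n$ assignments are enumerated for $n \le 20$ via subset-sum doubling
(exact p); beyond that, Monte Carlo sampling includes the observed
assignment in the denominator so $p \ge 1/(n_\mathrm{perm}+1)$ and the
test remains valid. All-zero differences return $p = 1$ with a
degenerate flag. The rank-sum test uses midranks with tie correction;
exact enumeration of $\binom{n+m}{n}$ assignments when $n+m \le 12$
without ties, otherwise a continuity-corrected normal approximation.
`stats::wilcox.test` is used in the test suite as an independent
cross-check of the exact path, never as the implementation.

## Problem sizes and tolerances in the test suite

Scenes are kept small by design: tubes of 8–12 µm in 200×260–360 px
frames, 3–8 frame time series, and ground-truth-only (unrendered)
division scenarios for the 100-scenario frame-selection sweep — the
sidecar ground truth is sufficient for every downstream statistic, so
rendering is exercised where pixels matter and skipped where they do
not. Null calibration of the permutation test uses 2000 simulated
cohorts of 20 pairs at $\alpha = 0.05$, expecting a rejection rate in
[0.03, 0.07]. Recovery tolerances: 0.04 µm on noiseless calibers,
median relative error ≤ 10% at peak SNR ≈ 10, 0.05 on recovered
symmetry, 15% on rendered pearling SD.

## Known limitations

* Centerlines are inputs (annotations or generator truth); there is no
  automatic tracing. Scans perpendicular to a *wrong* centerline
  overestimate caliber by the secant factor of the angular error.
* The caliber of strongly curved segments (radius of curvature
  approaching the scan half-length) can pick up the far wall of the
  same axon; the nearest-peak rule mitigates but does not eliminate
  this.
* The arc model assumes a circular profile and exact border anchoring;
  its output is a geometric demonstration, not a fitted quantity.
* 16-bit TIFF quantization bounds stored-pixel error at ~1/65000 of
  the frame maximum — irrelevant for peak positions, but scenes with
  extreme dynamic range should raise the bit depth of the sidecar
  scale.
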