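---
title: "Deconvolution-free perfusion analysis of DSA sequences: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolution-free perfusion analysis of DSA sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioperf)
```

## The problem

Cerebral vasospasm after aneurysmal subarachnoid hemorrhage narrows the large
intracranial arteries and starves downstream tissue of blood. It is treated
in the angiography suite — typically by intra-arterial infusion of a
calcium-channel blocker such as verapamil through a microcatheter — but
whether a given infusion actually improved *perfusion* is usually judged by
eye, from the change in vessel caliber on the subtracted angiogram. That
proxy is unreliable: luminal diameter and tissue perfusion correlate only
loosely.

`angioperf` quantifies the hemodynamic effect directly from the digital
subtraction angiography (DSA) runs the operator is already acquiring. A DSA
cine run is a time series of 2-D projection frames in which iodinated
contrast transits the field of view; every pixel therefore carries a
time-intensity curve of that transit, and standard indicator-dilution
(bolus-tracking) analysis applies — without deconvolution, which 2-D DSA
geometry does not support well.

## Model

Raw frames $I_{x,y}(t)$ are converted to a nonnegative contrast proxy by
per-pixel baseline subtraction,

$$C_{x,y}(t) = \max\{0,\ b_{x,y} - I_{x,y}(t)\},$$

where $b_{x,y}$ is the mean of the first `baseline_frames` (default 2)
pre-injection frames. Subtracted angiograms render iodine *dark*, hence the
sign; inverted exports use the opposite polarity. Adding any constant to all
frames, or rescaling all intensities, changes nothing downstream: baselines
absorb offsets and every threshold below is relative.

Six quantities are computed per pixel from $C_{x,y}(t)$ inside a global
signal-integration window:

* **AT** (arrival time): the upward crossing of 5% of the curve peak from
  which the curve rises to its maximum.
* **TTP** (time-to-peak): the time of the earliest maximal sample.
* **TTD** (time-to-drain): the last downward crossing of 5% of peak after
  the maximum.
* **MTT** (mean transit time): the full width at half maximum — the time
  between the first upward and last downward crossings of half the peak.
  This is the *direct bolus-tracking* MTT, deliberately not the
  deconvolution MTT of CT/MR perfusion.
* **CBV** (relative cerebral blood volume): $\int C_{x,y}\,dt \big/ \int
  C_{\mathrm{AIF}}\,dt$, trapezoid rule on each curve's own sample grid over
  the shared window. The arterial input function $C_{\mathrm{AIF}}(t)$ is
  the mean contrast curve along an operator-placed line spanning the
  injected vessel (bilinear sub-pixel sampling; manual placement is a design
  choice — the vessel of record is known to the operator, and automatic
  segmentation is out of scope).
* **CBF**: $\mathrm{CBV}/\mathrm{MTT}$, by the central volume principle.
  Units are 1/s; CBV is dimensionless. Both are *relative* quantities —
  projection imaging does not support absolute ml/100 g/min calibration.

The integration window is detected once per study, on the spatial-mean
curve $g(t)$: it opens when $g$ first exceeds 5% of its peak and closes at
the first post-peak time after which every frame-to-frame change of $g$
stays below 1% of the peak, or at the end of the run, whichever is earlier.
"Arrest of signal changes" has no standard numerical definition; this
per-frame-change rule is our operationalization and is recorded in the map
metadata.

## Numerical choices

**Sub-sample precision.** DSA frame intervals (0.25–1 s) are coarse against
clinically relevant effects (0.3–1.6 s), so all threshold crossings are
located by linear interpolation between the bracketing samples. TTP remains
the earliest maximal *sample* (plateau ties break early); interpolation
cannot sharpen an extremum, so TTP carries quantization of at most half a
frame interval.

**Arrival under noise.** Subtraction noise is comparable to the 5% arrival
threshold at realistic contrast-to-noise ratios. The arrival crossing is
therefore taken as the *last* upward threshold crossing before the peak: on
a clean single-pass curve this is identical to the first crossing, but it
ignores isolated pre-arrival noise spikes, which otherwise drag AT toward
the window start and destroy pre/post arrival differences.

**Pixel validity.** A pixel enters the maps only if its contrast peak
exceeds `noise_floor_k` (default 3) times its own baseline-window standard
deviation and its FWHM is positive. Invalid pixels carry `NaN` — never 0,
which would masquerade as instant arrival — in every map, and the validity
mask is the single source of truth. Curves that have not drained (or not
fallen below half maximum) by the window end are truncated there and
flagged rather than discarded.

**Multi-peak curves.** The FWHM spans from the first upward to the last
downward half-maximum crossing, across all lobes. This is a documented
limitation for curves with recirculation humps.

## Quality control of study pairs

The exclusion rules used when selecting analyzable studies are automated in
`validate_pair()`:

* same projection view; identical frame geometry, with pixel spacing within
  1% when present (a proxy for unchanged magnification);
* patient motion: the median rigid translation between consecutive
  *baseline* frames, estimated by phase correlation, must stay below a
  threshold (default 2 px — the threshold is configurable because
  "significant motion" is not quantified in practice). Baseline frames only,
  because contrast arrival itself changes intensity and would confound
  registration of later frames;
* full transit captured: the frame-mean contrast curve must fall back below
  a fraction (default 0.2) of its peak before the run ends, otherwise the
  venous phase was clipped.

Motion is screened, never corrected: 2-D projections do not support
reliable motion correction, so contaminated pairs are excluded (or forced
through with an explicit flag and a warning).

## Territory statistics

Vascular territories (MCA, ACA, PCA, vertebrobasilar) are supplied as
raster masks or polygon JSON and summarized per metric over valid in-ROI
pixels: n, mean, median, sd (sample, $n-1$), skew and *excess* kurtosis
(adjusted Fisher–Pearson; zero-variance distributions report 0). The
pre/post comparison reports, per metric, the change in means with a Welch
unequal-variance two-sample test and its 95% CI half-width. Welch is a
deliberate choice: pre and post pixel sets are not in spatial
correspondence (nothing is registered), so a paired test is unjustified —
though a paired mode exists for registered phantoms. Pixel values within a
territory are spatially autocorrelated, so pixel-level p-values are
anticonservative; they are reported as is (matching field practice), with
an optional every-k-th-pixel subsampling as a crude effective-sample-size
correction, off by default. Across interventions, `aggregate_cases()`
averages per-case mean changes with a t-based 95% CI.

## Rendered maps

Pre/post map pairs are displayed on one shared scale: bounds are the 2nd
and 98th percentiles of the pooled valid pixels of both studies (robust
rather than min/max, because subtraction noise produces extreme outliers
that would crush the display range). The package ships a fixed 256-entry
red–yellow–blue–black lookup table; timing metrics traverse it low-to-high
and flow metrics high-to-low, so *red always means better perfusion* (early
arrival, short transit, high volume/flow) and blue/black worse. Invalid
pixels render black. The four-panel review figure tiles pre-AP, pre-LAT,
post-LAT, post-AP clockwise from top-left with a shared colorbar.

## The digital flow phantom

No DSA study data are distributable, so everything is validated against a
synthetic phantom with known kinetics. Each territory's transit curve is a
peak-normalized gamma-variate

$$C(t) = A\left(\frac{t - t_0}{\alpha\beta}\right)^{\!\alpha}
  e^{\,\alpha - (t - t_0)/\beta},\qquad t > t_0,$$

the canonical single-pass indicator-dilution shape, parameterized so the
peak equals $A$ exactly at $t_0 + \alpha\beta$ — amplitude and timing are
independently controllable. Frames are rendered dark-contrast around a
baseline of 100 with additive Gaussian subtraction noise (sd 2 by default)
and a static low-spatial-frequency "residual anatomy" texture (sd 5).
The texture matters: perfectly flat baselines carry no information for
phase correlation, whereas real subtracted angiograms always retain
structured subtraction residue — it is exactly what motion estimation locks
onto. Optional per-frame integer rigid shifts emulate patient motion.

The default phantom is 128×128 pixels × 40 frames at dt = 0.25 s, with an
MCA-like territory (α = 2, β = 1.25 s, t₀ = 2.2 s, A = 30), an ACA-like
territory (α = 2, β = 1.1 s, t₀ = 2.4 s) and an arterial segment
(α = 2, β = 0.7 s, t₀ = 1.6 s, A = 60) carrying the AIF; kinetics were
chosen so transit completes within the 10 s run and territory FWHMs sit in
the 3–4.5 s range typical of vasospastic hemispheres. The default pre/post
deltas (`default_deltas()`) shorten onset and scale so that arrival moves
≈ −0.6 s, peak ≈ −1.2 s and transit ≈ −1.1 s — the magnitude of reported
intervention effects. Ground truth for every metric is computed by a
dense-grid (dt = 10⁻⁴ s) brute-force scan of the *analytic* curves, a code
path fully independent of the production metric functions.

What the phantom does *not* emulate: X-ray physics, anatomically realistic
vascular trees, overlapping territories along the projection axis,
recirculation, and non-rigid motion. Passing phantom tests therefore
demonstrates correctness of the computation, not clinical validity on
patient data.

## Problem sizes and determinism

The test suite and acceptance script run the default 128×128×40 phantom
pair (a few seconds end to end), 100-curve oracle-equivalence sweeps at
dt = 0.25 s against dt = 10⁻⁴ s references, and 200-replicate null
calibration of the Welch test at n = 10⁴ per arm. All randomness flows
from explicit integer seeds; a seeded phantom regenerates bit-identically.
Map computation is vectorized over pixels (matrix crossings rather than
per-pixel loops); a 1024×1024 frame raster is within interactive reach.

## Known limitations

* A 2-D projection aggregates all territories along each ray; the metrics
  are projection-weighted composites, not tissue-level values.
* TTP is quantized to the frame grid (≤ dt/2 error).
* CBV/CBF are relative; cross-patient comparison requires identical
  injection protocols.
* The FWHM-based MTT differs numerically from deconvolution MTT; the two
  should not be mixed across modalities.
* Pixel-level significance tests ignore spatial autocorrelation (see
  above); interpret p-values as descriptive.
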