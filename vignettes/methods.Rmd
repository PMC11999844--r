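---
title: "Methods: time–intensity curve analysis for CEUS during kidney perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time–intensity curve analysis for CEUS during kidney perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceustic)
```

## The measurement and its model

Contrast-enhanced ultrasound during normothermic machine perfusion records,
for each region of interest (ROI), the mean pixel intensity in decibels on
every timestamped frame of a cine loop. After an arterial microbubble bolus
the intensity in a well-perfused region rises quickly to a peak and washes
out; poorly perfused tissue enhances later and less. The analysis treats
each ROI trace independently and makes three assumptions:

* intensity is non-negative (contrast mode has essentially zero background
  signal), so negative raw values indicate an export problem and negative
  smoother overshoot is clamped;
* all ROIs of one kidney share the cine loop's frame times, so their traces
  share a time vector;
* the first-pass bolus dominates the 30 s analysis window — wash-out and
  recirculation beyond the window are out of scope.

No parametric curve is fit to real data. The smoother is deliberately
non-parametric; the gamma-variate appears only in the simulator, where a
known truth is needed.

## Time zero and the analysis window

Operators conventionally set time zero to the frame where contrast first
appears in the segmental/interlobar arteries. A reproducible artifact
cannot depend on an operator, so `detect_time_zero()` provides a
deterministic surrogate: baseline is the mean of the first
`baseline_frames` (default 10) frames, and arrival is the first frame
exceeding baseline + `delta_db` (default 1 dB) that stays above threshold
for `sustain_frames` (default 2) consecutive frames. The sustain rule
rejects single-frame noise spikes; the baseline-relative threshold makes
detection invariant to constant intensity offsets. A manual time zero can
always be supplied instead (`rebase_and_truncate()`, or
`--time-zero <seconds>` on the command line). Clips are cut to a 30 s
window after time zero — comfortably longer than the time for all three
parenchymal regions to peak — and never padded.

Input validation is strict by design: duplicated or non-monotone
timestamps raise an error naming the offending row rather than being
averaged or re-sorted, because a per-frame export contains each frame once
and anything else indicates corruption. Traces shorter than 8 frames are
rejected as unfittable. Negative intensities are errors by default, with a
lenient clamp-to-zero mode for vendors whose exports dip marginally below
zero. Time units may be seconds (default) or milliseconds, declared
explicitly; no frame-rate assumption is ever made — all computations work
from the timestamps.

## The smoother

`fit_loess()` performs local polynomial regression with tricube weights,
evaluated *directly* at each of `grid_points` (default 1001) uniformly
spaced times spanning the data. At a grid time $x$, the
$q = \max(\text{min\_neighbors}, \lceil \text{span} \cdot n \rceil)$
nearest frames (ties in distance all included) receive weights
$w_i = (1 - (d_i/d_{max})^3)^3$ and the fitted value is the weighted
least-squares polynomial of degree 2 evaluated at $x$.

Choices worth recording:

* **span = 0.06.** At ~15 frames/s over 30 s ($n \approx 450$), the
  neighbourhood is ~27 frames, i.e. under two seconds of data — tight
  enough to track the bolus upslope, wide enough to suppress frame noise.
* **degree 2, gaussian family, zero robustness iterations.** Quadratic
  local fits capture the curvature at the peak without the boundary bias of
  local means; robustness iterations are unnecessary for dB-scale frame
  noise and would break the smoother's linearity in the response (a
  property the tests exploit).
* **Direct evaluation, not an interpolation surface.** Computing the exact
  local fit at every grid point costs more than interpolation-cell
  approximations but is deterministic and oracle-checkable: the tests
  compare it to an independent weighted-normal-equations implementation at
  $10^{-8}$.
* **Degenerate neighbourhoods.** `min_neighbors = degree + 2` guards short
  clips where $\lceil \text{span}\, n \rceil$ would underflow the local
  design. If the local design is still rank-deficient the degree is reduced
  by one at that grid point and the event recorded in the fit diagnostics;
  if all selected points coincide with $x$, the fitted value is their plain
  mean. The polynomial is solved in a basis centred at $x$ for numerical
  conditioning.
* **Evaluation grid.** Metrics are read from a fixed uniform grid so their
  resolution (30 s / 1000 ≈ 0.03 s) is independent of the loop's frame
  rate. `evaluate()` interpolates linearly between grid points and refuses
  to extrapolate.

## Metrics

From the smoothed curve, with negative values clamped to zero first:
peak intensity `PI` is the grid maximum; time-to-peak `TTP` the *earliest*
grid time attaining it (an explicit tie-break, relevant for plateaus);
`time_to_fraction` the earliest grid time reaching `fraction · PI`
(default 0.9 — "time to 90 % of peak" — configurable because the rising
limb's steepness is of independent interest; by the earliest-time rule it
can never exceed TTP); and AUC the trapezoidal integral of the clamped
curve over the full window. AUC is computed over the whole 30 s window
rather than to a fixed post-peak horizon: the window is already
standardised, and a fixed horizon would silently truncate slow kidneys. A
completely flat zero curve has no meaningful TTP and raises a
degenerate-data error rather than returning arbitrary numbers.

## The CEUS score

Peak intensity (dB) and time-to-peak (s) live on incommensurate scales, so
each is z-scored against a cohort reference — per region, the mean and
standard deviation of PI and of TTP across kidneys. The sample (n−1)
standard deviation is used, the usual convention for small cohorts. A
region's score is $z_{PI} - z_{TTP}$ and the overall score is the sum over
cortex, outer medulla and inner medulla. Against a self-built reference the
construction forces per-region z-means of 0 and SDs of 1, and all scores
sum to zero across the cohort — properties the tests assert to $10^{-9}$.
The reference can also be saved (`write_reference_table()`) and reused, so
a new kidney can be scored against a historical cohort; a cohort with zero
variance in any region (identical kidneys) is degenerate and refused. AUC
and time-to-fraction are reported alongside but intentionally do not enter
the score.

## ROI extraction from cine stacks

Where only the cine loop is available, `extract_tic()` reimplements the
quantification step: rasterise each ROI to a pixel mask, then average the
pixel values under the mask per frame. Geometry conventions are explicit
because vendor software does not document its own: a pixel belongs to a
mask iff its *centre* lies inside the shape; squares use half-open
`[min, max)` edges so adjacent squares never share pixels (a 5 × 5 mm
square at 0.5 mm/px is exactly 100 pixels regardless of placement);
polygons use the even-odd rule. Partial-pixel weighting was rejected in
favour of pixel-centre membership because it is deterministic and checkable
against a per-pixel oracle; at clinical pixel sizes the difference is below
the frame noise. Stacks are accepted as in-memory arrays or multi-page
TIFF with a `frame,time_s` sidecar table — a portable, tooling-friendly
interchange for exported loops; the mask and averaging logic is
format-independent. The medulla is drawn as two separate polygons (outer,
inner) by the operator; the package does not attempt to split one polygon
automatically.

## The synthetic cohort generator

`simulate_cohort()` emulates the *statistical structure* of a perfusion
study, not ultrasound physics. Per kidney a latent injury value
$I \sim U(0,1)$ is drawn. Per region, baseline bolus parameters are drawn
around region-typical means — cortex brightest and earliest (A ≈ 10 dB,
arrival ≈ 3 s, rise ≈ 4 s), outer then inner medulla dimmer and later —
with residual kidney-to-kidney SDs of 0.8 dB on amplitude, 0.3 s on
arrival and 0.5 s on rise. These SDs represent the spread left over in a
single-centre cohort with a standardised perfusion and imaging protocol
once the injury gradient is accounted for. Injury then multiplies
amplitude by $1 - 0.4 I$ and rise time by $1 + 0.6 I$ — injured kidneys
enhance less and more slowly — and the outcome variable (an NGAL-like
injury marker) is $100 I$ plus gaussian noise of SD 10. Traces sample the
gamma-variate at 15 frames/s over 30 s with 0.5 dB frame noise, clamped at
zero. All randomness flows from one explicit seed; no function touches the
global RNG state.

What passing tests on this generator do **not** show: robustness to
speckle and attenuation, motion between frames, microbubble destruction,
recirculation humps, operator variability in ROI placement, or
non-gaussian outcome distributions. Those require real loops.

## Statistics

Pearson's r with the exact two-sided p from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom; $|r| = 1$ maps to
$p = 0$. Two-sided is the appropriate default for these correlations and
reproduces published small-cohort p-values when recomputed from their
(r, n) pairs. `p_from_r()` is exposed separately precisely so printed
pairs are checkable. Missing kidneys are deleted pairwise with every
exclusion logged; no multiple-testing correction is applied (results are
per-pair with raw p-values), but a note is attached whenever more than 10
pairs are computed, as a prompt that type-1 error inflation needs thought.

## Problem sizes used in the test-suite

The oracle-equivalence suite runs 100 seeded random instances of 300
frames; noisy parameter recovery uses 200 seeded replicates at 15 frames/s
over 30 s; the end-to-end pipeline check uses a 10-kidney cohort. These
sizes match the data regime the package targets (a perfusion cohort is
5–10 kidneys; a 30 s loop at video frame rate is a few hundred frames)
while keeping the default test run fast.

## Command-line interface

`ceustic analyze | score | simulate | correlate | extract-roi` are thin
wrappers over the library functions (equivalence is itself tested), with a
YAML configuration file whose unknown keys are rejected, flags overriding
config, a `run.log` per run recording configuration, package version and
the time zero used, and exit statuses that separate validation errors (2)
from degenerate-data errors (3) and unexpected failures (1) so pipelines
can branch on failure class. Report plots are accompanied by
machine-readable curve tables, so downstream checks never need image
comparison.
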