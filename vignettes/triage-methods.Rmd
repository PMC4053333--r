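---
title: "Triage of camera-trap videos by pixel variation: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of camera-trap videos by pixel variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vidtriage)
```

## The problem and the model

A motion-triggered trail camera aimed at a burrow, runway or foraging
site records a short clip whenever its sensor fires. Wind, rain,
reflections and rippling water fire it too, so a majority of clips can
contain no animal at all, and a field season easily yields thousands
of 15-second recordings that someone must screen. `vidtriage`
automates the first, crudest screening decision: *did anything large
move in this clip?* It makes no attempt to recognize species — that is
a deliberate non-goal — and it discards only in one direction: a
recording below the threshold is declared non-target; a recording
above it is simply *kept*, with no inference about what it contains.

The model is that a large, slowly moving animal perturbs many pixels
over many frames, while an empty scene varies only through sensor
noise and background motion. Each clip becomes a grayscale tensor
$A(x, y, t) \in [0, 1]$. Two preprocessing steps precede any
measurement:

1. **Leading-frame removal** (default 2 frames): trail cameras print a
   time stamp on the first frame and their exposure is unstable while
   starting, both of which would masquerade as motion. The removal
   happens *before* temporal pooling, so the contaminated frames never
   enter any average.
2. **Average pooling** by factors $(5, 5, 10)$ along $(x, y, t)$:
   pixel-level sensor noise, leaf flutter and glints are averaged away
   while the displacement of a subject spanning a large part of the
   frame survives. Averaging (not decimation) is essential — decimation
   would keep the noise. A non-divisible tail block is averaged over
   its actual size rather than dropped, so motion at the end of a clip
   still counts. For very small or very fast subjects these factors
   should be reduced (they are ordinary config parameters), since
   pooling that outscales the subject destroys exactly the signal
   being measured.

Two filters then summarize the motion energy:

* **Filter 1** compares every frame to the time-averaged frame
  $\bar A(x,y)$: $d(t) = \sum_{x,y} (A(x,y,t) - \bar A(x,y))^2$. A
  subject anywhere in the clip drags frames away from the average.
* **Filter 2** compares consecutive frames:
  $d(t) = \sum_{x,y} (A(x,y,t+1) - A(x,y,t))^2$. It responds to
  instantaneous change and is insensitive to slow illumination drift
  that Filter 1 partly absorbs into $\bar A$.

Both series reduce to the per-recording score

$$D = \operatorname{mean}_t d(t) - \min_t d(t).$$

The subtracted minimum is the clip's own baseline: a pond ripples in
every frame, so even its quietest frame carries variation, and
removing that floor makes $D$ comparable between restless and quiet
backgrounds. The mean (rather than the sum) makes $D$ independent of
clip length. Two alternative reductions (`max_minus_min`,
`sum_minus_n_min`) are kept behind the `reduction` switch of
`preprocess_config()` because the reduction is the least constrained
part of the design; all three vanish on a constant series.

Useful exact properties, all enforced by tests: $D \ge 0$ with
equality iff $d(t)$ is constant; both filters are invariant under a
global additive intensity shift; scaling all intensities by $s$ scales
$D$ by exactly $s^2$ (so the $[0,1]$ normalization merely fixes the
unit of $D$ and cannot change any ranking).

## Classification, ROC and the operating point

The discard rule is $D < \theta$, *strictly*: a tie is kept for
inspection, because the asymmetric cost in this application is losing
footage of the study animal. Following the convention of triage, the
**non-target** recording is the positive class: the TP-rate is the
fraction of non-target recordings correctly discarded (the workload
saved) and the FP-rate is the fraction of target recordings wrongly
discarded (the data lost).

Candidate thresholds are the midpoints between consecutive distinct
$D$ values plus $\pm\infty$ sentinels, so every achievable operating
point appears exactly once and the achieved rates are invariant to
infinitesimal perturbation of the threshold. `threshold_for_fp()`
selects the *largest* candidate whose FP-rate does not exceed the
tolerance — discarding is maximized subject to the tolerated loss,
rather than aiming "nearest" to the tolerance, again because the cost
asymmetry is one-sided. A consequence worth knowing: with $n$ labeled
target recordings, the rule will admit up to
$\lfloor \text{tol} \cdot n \rfloor$ targets below the threshold even
when the classes are perfectly separable; a tolerance finer than $1/n$
forces a zero achieved FP-rate. Time savings are the summed duration
of every discarded recording, right or wrong — neither is watched.

Dry and wet camera locations (less or more than 10 % visible water
surface) are analyzed by the same operations on filtered recording
subsets; wet backgrounds have a higher variation floor and overlap the
target distribution more, so the achievable TP-rate at fixed FP-rate
is lower there.

## Bootstrap of the FP-rate

The threshold is calibrated once, but future recordings are new draws
from a similar population. `bootstrap_fp_rate()` resamples the labeled
dataset **with replacement** (the standard bootstrap; the resampling
flavor is a design choice, stated here because subsampling without
replacement would shrink the variance), of default size 500 for 1000
replicates, and recomputes the FP-rate at the *fixed* threshold each
time. Replicates without a single target recording leave the rate
undefined; they are skipped and counted rather than imputed — at
realistic sizes (hundreds of targets in a ~1000-recording population)
the event has negligible probability, and skipping cannot bias the
comparisons made with the summary. The summary reports the mean,
sample standard deviation ($n-1$), and empirical 2.5/97.5 percentiles
(type-7 linear interpolation — R's default; the choice is immaterial
at 1000 replicates). The whole procedure is a deterministic function
of its seed.

Because the threshold is fixed, each replicate's FP-rate is, in
distribution, a two-stage binomial: the number of targets in the
resample is $B \sim \mathrm{Bin}(n_{sub}, p_{target})$ and the
discards among them are $\mathrm{Bin}(B, \widehat{fp})$. The test
suite checks the replicate distribution against this construction by
Kolmogorov–Smirnov distance, and that the bootstrap mean converges to
the empirical FP-rate.

## What the synthetic data emulates — and what it does not

Two generators provide labeled inputs at different levels.

`generate_scene()` renders a clip: mid-gray background with Gaussian
sensor noise (sd 0.02 per pixel per frame — visible speckle on an
8-bit IR frame without swamping it); for wet scenes a sinusoidal
ripple field over the lower 40 % of the frame whose phase drifts
across frames, adding genuine temporal variance the way water does;
optionally a rectangle of 30 % frame width moving at 1.5 px/frame with
contrast 0.4 — large and slow, as a beaver-sized mammal a few meters
from the camera appears. The default desk-scale clip is 96 × 64 × 60
at 0.25 s/frame (a 15 s clip), chosen so the full end-to-end test
suite runs in well under a minute; the geometry is deliberately
abstract because both filters are shape-agnostic. Scenes sharing a
seed share their noise realization exactly, enabling paired
with/without-subject comparisons. A clip is labeled `target` only when
its subject spans at least 15 % of the frame width; smaller objects
play the role of non-target species.

`generate_population()` skips the video layer and draws per-recording
$D$ scores directly: log-normal for both classes ($D$ is non-negative
and right-skewed, being a baseline-corrected mean of sums of squares),
targets centered above non-targets, default class sizes 1043 targets
and 948 non-targets of 15 s — a season-scale campaign. The condition
presets encode only *ordering* constraints, not measured
distributions: wet non-targets (meanlog 0.2, sdlog 0.8) sit higher and
overlap the target distribution (meanlog 1.0, sdlog 0.6) more than dry
non-targets (meanlog −0.6, sdlog 0.6).

Passing tests on these generators therefore demonstrate that the
*machinery* is correct — the filters measure what they claim, the ROC
and operating-point logic is exact, the bootstrap has the right
distribution — and that discrimination holds when the data have the
assumed structure. They do not demonstrate field performance: real
footage has autocorrelated sensor noise, illumination drift, rain on
the lens, animals that stand still, and class overlap of unknown
shape. The achievable TP-rate on real data must always be read off a
ROC curve built from that study's own labeled subset.

## Numerical and degenerate-input choices

* Sums of squares use R's native accumulation (long-double
  internally), which holds the brute-force oracle agreement to within
  $10^{-9}$ relative error on the tested sizes.
* $D$ is clamped at 0 against floating-point underflow of
  `mean - min`.
* A video must keep at least one frame after leading-frame removal
  (Filter 2 needs two); violations raise degenerate-video errors
  rather than returning empty series.
* Frame rate is never assumed: still-frame sequences carry no timing
  metadata, so `frame_period` is an explicit argument and durations
  are computed, not guessed.
* An 8-bit image round-trip quantizes intensities to 1/255; tests
  treat that as the decoding tolerance.
* Missing $D$ values fail loudly (naming the recording) everywhere
  rather than being dropped silently; batch computation
  (`compute_d_table()`) is the one place where per-file failure is
  non-fatal, because one corrupt file must not cost a night's run.

## Known limitations

* No in-process video-container decoding: AVI and friends are exported
  to frame sequences first. The ingestion contract (lexicographic
  frame order, PNG/TIFF, multi-page TIFF) is small and testable.
* A motionless animal is indistinguishable from an empty scene by
  construction; the method relies on arrival/departure movement within
  the clip.
* Once background variation exceeds subject-induced variation (storm
  on open water), no threshold separates the classes; the ROC curve
  makes this visible but the method cannot fix it.
* The single-score population surrogate assigns the same draw to both
  filter columns; it models each filter's score distribution, not the
  correlation structure between filters.
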