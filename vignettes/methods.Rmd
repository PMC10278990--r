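---
title: "Models and methods behind caflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind caflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(caflux)
```

caflux analyses two-photon Ca²⁺ recordings of cortical astrocytes and
neurons during locomotion. This vignette explains the models the package
implements, the parameters that matter, what the synthetic generator does
and does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Preprocessing model

Raw movies are acquired at 30 frames/s, 512 × 512 px, in two channels:
green (GCaMP6f) and red (autofluorescence, a pure morphology marker).
Processing order is **bin → motion-correct → denoise**:

1. **Temporal binning** sums non-overlapping batches of 5 frames
   (30 Hz → 6 Hz), raising photon counts per frame fivefold before any
   model-based step.
2. **Motion correction** is rigid and integer-valued. Shifts are estimated
   on the red channel because it carries no activity-driven intensity
   changes. The red stack is first denoised by projecting each frame onto
   its leading 50 spatial principal components; the mean image and the
   components are all smoothed with a σ = 1 px Gaussian, so each
   reconstructed frame is a consistently blurred image. (Smoothing only
   the deviations from the mean would shrink apparent shifts toward zero —
   a subtle failure mode we verified on synthetic drift.) Each frame is
   then phase-correlated against the per-pixel median template. The
   cross-power spectrum is regularized as `R / (|R| + 0.5 · mean|R|)`:
   full spectral whitening amplifies the noise-dominated high frequencies
   and misses rare large shifts, while this regularized form interpolates
   between matched filtering and phase correlation. A second pass
   re-estimates residual shifts against the realigned template. Shifts are
   anchored so frame 1 is (0, 0) and applied to both channels with
   replicated borders (zero padding would bias ΔF/F at the edges).
3. **Denoising** variance-stabilizes the counts with the Anscombe
   transform `x → 2√(x + 3/8)`, approximates each overlapping 64-px patch
   (50% overlap) by a rank-8 truncated SVD of its pixels × time matrix,
   smooths the spatial factors with a σ = 0.5 px Gaussian, blends
   overlapping reconstructions with weights that sum to one at every
   pixel, and inverts the transform. The patch size, overlap and rank are
   free parameters of the method; rank 8 comfortably exceeds the temporal
   complexity of the scenes we simulate. The spatial-factor σ deserves a
   note: we default to 0.5 px — about half the optical point-spread scale —
   because σ = 1 px measurably degrades reconstructions of PSF-limited
   fine processes (the MSE against clean truth *rises* above the raw data
   on our synthetic scenes), while 0.5 px suppresses pixel-level artifacts
   in the factors without erasing resolvable structure.

## ΔF/F model

The baseline F₀ of each pixel is a *lower envelope*: a running minimum
over a window of σ_t = 15 s, Gaussian-smoothed with the same σ_t. The
minimum window slides fully inside the record near the edges so that every
time point sees a full-length window; the negative bias of a windowed
minimum is then uniform and removable. The removal is the *mode
correction*: F₀ is shifted per pixel by the constant that brings the mode
of the residuals F − F₀ to zero, on the rationale that the most frequent
fluctuations are noise while true Ca²⁺ events are sparse. The mode is
estimated from a histogram with bin width equal to half the robust
(MAD-based) residual SD — fine enough to localize the noise peak, coarse
enough to be stable. ΔF/F = (F − F₀)/F₀ × 100%.

Active segments are 8-connected clusters of stained pixels with
ΔF/F ≥ 15%, **strictly** larger than 16 pixels, chained across frames by
≥ 1 px spatial overlap and retained only if the chain spans ≥ 3
consecutive frames. These are the most permissive readings of "cluster"
and "overlap", and the three thresholds are enforced bit-exactly (the
test suite checks 16 px vs 17 px, 2 vs 3 frames, and 14.999 vs 15.0%).
The *active area* is the retained pixels' percentage of the stained area.
The stained mask is thresholded from the mean image at background
(median) + 20% of the background-to-99th-percentile range — a
scale-invariant rule chosen over Otsu because between-class thresholds cut
off dim process edges.

## Astrocyte branch

Per cell, ΔF/F is averaged over the soma mask and the processes mask
(domain minus soma). Both traces are normalized to their peaks; the
**onset latency** is the difference between the times each normalized
trace first crosses 0.15, with linear interpolation between samples,
positive when the processes lead. The latency search can be windowed
around a locomotion episode (± 15 s) when recordings contain several
responses. Oscillation prominence is the mean Morlet continuous-wavelet
power (center frequency parameter 6, the conventional choice; nine
frequencies spanning 0.1–0.3 Hz) over the interval where the trace exceeds
15% of its peak. Cell size is the maximum Feret diameter — the largest
pairwise distance between mask pixel centers, computed on the convex hull
and verified against brute force. The latency–size relation is an
ordinary least-squares regression.

## Neuron branch

Neuronal movies are decomposed into **activity units** — synchronously
active structures, not necessarily single cells. The factorization is a
non-negative matrix factorization without temporal-kinetics constraints,
solved by hierarchical alternating least squares (HALS; monotone in the
squared error) from a deterministic nndsvd initialization. It runs first
in overlapping square patches (one extra component per patch absorbs
diffuse background and is dropped, as are components whose support covers
more than half the patch), then once more on the whole frame initialized
from the patch solution. Footprints are clipped with Li's minimum
cross-entropy threshold on their nonzero pixels; the iterative fixed point
is polished by discrete descent over the data-derived candidate
thresholds, which resolves near-ties with the exhaustive search (the test
suite compares the two on random histograms). Components with trace peak
below 6 robust SDs are discarded, and the survivors' z-scored traces are
merged by Ward-linkage hierarchical clustering into the requested number
of final units (default 12; per-patch component counts scale with patch
area from the default 12 per 100 × 100 px). Units are classified
locomotion-active or quiescent-active by comparing mean trace activity in
the two behavioral states.

## Locomotion statistics

Episodes are segmented from the lightly smoothed speed with a 0.5 cm/s
threshold; sub-threshold gaps < 0.5 s are merged and runs < 1 s dropped
(the segmentation criteria are not part of the underlying method and are
exposed in the configuration). The Q/L ratio divides mean activity over
all quiescent time by mean activity over all locomotion time. The
speed–ΔF/F cross-correlation is Pearson-normalized per lag so the peak
lies in [−1, 1]; positive lag means activity follows speed. Paired runs
are consecutive locomotion episodes whose gap is strictly < 30 s, paired
greedily left to right. The PRR uses response windows from episode onset
to offset + 10 s (accommodating the delayed astrocytic response), capped
at the next episode's onset; the peak response is the default statistic
and the window mean is reported alongside, reconciling the two natural
readings of "response". The Mann–Whitney U test enumerates all
assignments exactly for pooled n ≤ 12 (ties handled by permuting the
observed values) and otherwise uses the tie-corrected normal approximation
with continuity correction. Group-level mixed-effects comparisons are out
of scope; the package emits tidy per-episode and per-cell tables suitable
for any mixed-model tool.

## The synthetic generator

The generator is the package's ground-truth instrument. It emulates:
alternating exponential-length runs (mean 15 s) and quiescence (mean
45 s), with ordinary inter-run gaps kept above 30 s so that only
deliberately generated pairs (gap ~15 s, always < 30 s) count as closely
timed; trapezoidal 10 cm/s speed bumps and exactly zero quiescent speed;
star-shaped astrocyte domains (soma disk + radial arms) and curvilinear
neuronal footprints, blurred by a σ = 0.8 px optical PSF (ground-truth
masks stay binary); difference-of-exponentials Ca²⁺ transients (astrocyte
rise 2 s, decay 4 s; neuronal rise 0.05 s, decay 0.3 s — GCaMP6f-scale
kinetics); process onset 1 s after run onset with the soma following
after a configurable centripetal delay (default 4.7 s) at 2.7× amplitude,
with an amplitude-modulated 0.2 Hz oscillation on the somatic transient;
paired-run depletion scaling the second response by α (default 0.32);
astrocytic response amplitude saturating with run duration (full size
from 10 s), since brief runs do not evoke full-blown astrocytic events;
neuronal locomotion-active units following the speed envelope with
near-zero lag, run-to-run gain variability and occasional non-participation
(perfectly collinear traces would make spatial demixing unidentifiable —
synchronous units are by definition one activity unit); quiescent-active
units firing Poisson events (0.4 Hz) outside runs; and a camera applying
an integer rigid drift random walk (same shift to both channels, clipped,
starting at zero) followed by Poisson photon noise and Gaussian read
noise, rounded to non-negative counts.

Episode-model and spontaneous-rate defaults were calibrated so that the
generator reproduces the Q/L scale reported for the two cell classes
(astrocytes ≈ 0.07, neurons ≈ 0.18) — these are exactly the phenomena the
generator exists to emulate. The soma amplification (2.7) and centripetal
delay (4.7 s) defaults equal the reported median soma/process peak ratio
and soma–process latency.

What it does **not** emulate: vascular or neuropil background,
photobleaching, non-rigid deformation, subcellular microdomain events,
inter-animal variability, or anticipatory (pre-run) neuronal activity.
Passing recovery tests on this generator therefore demonstrates the
pipeline's correctness and calibration on data satisfying its assumptions,
not performance on every artifact of real recordings.

## Numerical choices and degenerate inputs

- Truncated SVDs are computed from the Gram matrix of the smaller side;
  ranks are clipped (with a warning) when they exceed what the data
  supports.
- Translation uses replicated borders everywhere, and shift series are
  anchored at frame 1 = (0, 0).
- `anscombe()` rejects negative input; the patch-SVD chain clips negative
  reconstructions to zero before inverting.
- Featureless references yield zero shifts with a warning; empty
  compartments, empty masks and zero-variance regression inputs are
  errors; traces that never cross the onset fraction yield `NA` latency
  and are excluded from summaries.
- Ward clustering uses `ward.D2` on Euclidean distances of z-scored
  traces (the classical Ward requirement); zero-variance traces z-score
  to zero rather than NaN.
- All generators are pure functions of (configuration, seed), derive
  their sub-seeds from the configured seed, and restore the caller's RNG
  state.

## Problem sizes

The test suite and acceptance script run the full pipeline on movies of
36–64 px and 60–180 s — sizes chosen so the whole suite completes in
minutes on one core. Every phenomenon being tested (shift recovery,
envelope bias, latency, band power, depletion, segmentation) is
scale-free in the field of view and recording length, so these sizes
exercise the same code paths as full-scale data; the line-scan
visualization and the exact 512 × 512 geometry are the only aspects not
covered at full scale.

## Known limitations

- Motion correction is integer-pixel and rigid; resonant-scanner line
  distortions and slow non-rigid drift are out of scope.
- The background model in the factorization is a single unconstrained
  component per patch; structured neuropil contamination would call for a
  dedicated background rank.
- The mode-based bias correction assumes events are sparse per pixel; a
  pixel active most of the time would have its baseline overestimated.
- The exact Mann–Whitney branch enumerates up to pooled n = 12; beyond
  that the normal approximation (tie-corrected, continuity-corrected) is
  used.
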