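# caflux

Analysis of two-photon Ca²⁺ imaging of cortical astrocytes and neurons in
head-fixed, behaving mice. The package covers the full path from raw
two-channel movies (GCaMP6f fluorescence plus red autofluorescence) and a
locomotion speed trace to the statistics that characterize how the two cell
classes couple to running:

- **Preprocessing** — temporal binning (summing non-overlapping batches of
  5 frames), rigid motion correction by phase correlation against the
  denoised autofluorescence channel, and Anscombe/patch-SVD denoising
  (variance stabilization, per-patch truncated SVD with smoothed spatial
  factors, weighted blending of overlapping patches).
- **ΔF/F and active area** — the per-pixel baseline F₀ is a lower envelope
  through local minima smoothed with σ = 15 s, then shifted so the mode of
  the residuals is zero (noise dominates the histogram; true Ca²⁺ events
  are sparse); ΔF/F = (F − F₀)/F₀ × 100%. Active segments are 8-connected
  clusters with ΔF/F ≥ 15%, strictly larger than 16 pixels, persisting with
  spatial overlap for at least 3 consecutive frames; the *active area* is
  their fraction of the stained field per frame.
- **Astrocyte branch** — soma and process (domain minus soma) timecourses,
  the soma–process onset latency measured where each peak-normalized trace
  first reaches 15% of its maximum (positive latency = processes lead,
  i.e. centripetal propagation), Morlet wavelet band power in 0.1–0.3 Hz
  over the active interval, maximum Feret diameter, and the latency-vs-size
  regression.
- **Neuron branch** — patch-based non-negative factorization (HALS updates,
  nndsvd initialization, one background component per patch), whole-frame
  refinement from the patch solution, Li minimum-cross-entropy clipping of
  each spatial footprint, and Ward-linkage merging of component dynamics
  into final activity units, classified as locomotion- or quiescent-active.
- **Locomotion statistics** — episode segmentation, per-episode means, the
  Q/L ratio (mean activity in quiescence / mean activity in locomotion),
  speed–ΔF/F cross-correlation peak and lag, paired-run detection (gap
  strictly < 30 s) and the paired-run ratio PRR = response₂/response₁, and
  a Mann–Whitney U test with an exact small-sample branch.
- **Synthetic recordings** — a generator that emulates the experiment
  (30 Hz two-channel acquisition, Poisson–Gaussian camera, rigid drift,
  astrocytes with delayed amplified oscillating somatic responses and
  paired-run depletion, neuronal units with near-zero-lag responses or high
  quiescent activity) with complete ground truth, so every stage has a
  parameter-recovery test.

## Worked example

A synthetic astrocyte recording, processed end to end:

```r
library(caflux)

cfg <- scenario_config(duration_s = 80, fs_raw = 30, fov = 64,
                       n_astro = 1, n_neuro_units = 0,
                       mean_quiet_s = 25, mean_run_s = 8,
                       domain_radius_px = 14, soma_radius_px = 4, seed = 101)
rec <- simulate_recording(cfg)

pre <- preprocess_movies(rec$noisy$green, rec$noisy$red, batch = 5,
                         patch = 32, rank = 8)
d   <- dff_movie_pipeline(pre$green)
tr  <- compartment_traces(d, rec$truth$scene$astro[[1]])
lat <- onset_latency(normalize_to_peak(tr$soma),
                     normalize_to_peak(tr$processes), tr$fs)
cat(sprintf("soma peak %.0f%%, process peak %.0f%%, latency %.2f s\n",
            max(tr$soma), max(tr$processes), lat))
```

```
soma peak 342%, process peak 108%, latency 4.56 s
```

The configured soma amplification (2.7×) and centripetal delay (4.7 s)
are recovered from the noisy movie: the soma peaks at roughly 3 times the
process peak and its onset lags the processes by close to the injected
delay. (Peaks here are dimmer than the configured 170%/459% because this
scene's single run is short, and the generator scales response amplitude
with run duration.)

The `analysis/` directory holds the numbered drivers that reproduce the
full workflow on example data (`01_simulate.R` … `06_runstats.R`), writing
tables under `results/`.

## Conventions

- Movies are `H × W × T` arrays wrapped in `ca_movie` (frame rate, channel).
- Frame *i* covers `[i, i+1)/fs`; CSV times are frame-start seconds and
  frame indices are 0-based.
- ROI label TIFFs pair domain label `i` with soma label `i + 1000`.
- Multi-page TIFF movies are 16-bit; intensities are integer counts.
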