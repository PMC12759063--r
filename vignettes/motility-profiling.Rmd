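---
title: "Methods: motility metrics, behavioral profiling, and depth recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motility metrics, behavioral profiling, and depth recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivtk)
```

This vignette documents the models, algorithms and parameter choices behind
`ivtk`, in the order data flows through the toolkit.

## 1. Tracks and whole-track metrics

A track is a time-ordered sequence of positions $(t_i, x_i, y_i[, z_i])$
with times in seconds and positions in micrometres. Step $i$ has vector
$\Delta p_i = p_{i+1} - p_i$, length $\ell_i = \lVert\Delta p_i\rVert$ and
duration $\Delta t_i$. The whole-track metrics are:

- **Speed** $= \sum_i \ell_i \,/\, (T/60)$ in µm/min, where $T$ is the
  track duration in seconds — total path length over total time.
- **Directionality** $= \lVert p_N - p_1 \rVert \,/\, \sum_i \ell_i$, the
  straight-line displacement divided by the path length; 1 for perfectly
  straight motion, near 0 for confined motion. Defined as 0 when the path
  length is 0.
- **Arrest coefficient**: the duration-weighted fraction of steps whose
  instantaneous speed $60\,\ell_i/\Delta t_i$ falls below a threshold,
  default 2 µm/min — the conventional cutoff separating arrested from
  motile leukocytes. Duration weighting makes the metric invariant to
  splitting a step in two.
- **Square displacement** $\lVert p_i - p_1\rVert^2$ per point, and
  **MSD** over lags for uniformly sampled tracks,
  $\mathrm{MSD}(k) = \langle \lVert p_{i+k}-p_i \rVert^2 \rangle_i$.
- **Velocity autocovariance**
  $\mathrm{acov}(k) = \langle v_i \cdot v_{i+k} \rangle_i$ with
  $v_i = \Delta p_i / \Delta t_i$ scaled to µm/min; flat for ballistic
  motion, decaying to 0 for uncorrelated motion.
- **Mean turning angle**: mean angle between consecutive non-zero steps,
  in degrees; 0 for straight motion, 90 in expectation for isotropic
  random walks. Zero-length steps are skipped rather than counted as 0°,
  since a pause carries no direction.

Speed estimates are sampling-rate dependent: coarser sampling straightens
out sub-interval wiggle, so measured speed can only decrease under
subsampling. `fit_speed_decay()` quantifies this with a single-exponential
fit $v(\Delta t) = a\,e^{b\Delta t}$ (Levenberg–Marquardt via
`minpack.lm::nlsLM`, initialized from the log-linear fit; constant input
short-circuits to the exact degenerate solution $b = 0$). Cross-condition
comparisons should therefore use a common sampling interval, which is why
the profiling pipeline resamples first.

`residual_speeds()` removes per-video imaging and tissue effects by
subtracting, within each video, the mean speed of a designated control
population from every record; videos lacking controls are reported as
errors rather than silently passed through.

## 2. Behavioral profiling

Whole-track averages conflate phenotypes (a run-and-pause cell and a
uniformly intermediate cell can share a mean speed), so profiling works on
windowed time series:

1. **Duration filter** — tracks shorter than 500 s are dropped (too few
   windows to characterize alternating behavior).
2. **Resampling** — linear interpolation onto a uniform 10 s grid anchored
   at the first time point, making feature series comparable across
   heterogeneous acquisition rates.
3. **Windowing** — 50 s sliding windows (5 samples, stride 1), giving
   $W = S - 4$ windows for $S$ samples. Four features per window:
   directionality, square displacement (window end vs. start), mean
   speed, and an arrest score $1/(\mathrm{MSD}_w + \varepsilon)$ with
   $\varepsilon = 10^{-3}$ µm² bounding the score at $10^3$ for frozen
   windows.
4. **Pooled z-scoring** — features are standardized using means and SDs
   pooled over all windows of all tracks, so that amplitude differences
   between features do not dominate the distance; constant features
   degenerate to zero rather than NaN. The fitted center/scale can be
   replayed onto held-out tracks.
5. **DTW distances** — dependent multivariate dynamic time warping with
   Euclidean local cost between feature vectors, computed in C++ with a
   rolling two-row dynamic program ($O(nm)$ time, $O(\min(n,m))$ memory).
   DTW aligns behavioral sequences that differ in phase (a pause early
   vs. late) that lock-step distances would penalize.
6. **2D embedding** — the DTW matrix is embedded by classical metric
   multidimensional scaling (`stats::cmdscale`) after local distance
   scaling $D_{ij}/\sqrt{s_i s_j}$, where $s_i$ is the distance to the
   5th nearest neighbor. The local scaling equalizes per-cluster density:
   without it, a tight cloud of near-identical series (e.g. highly
   persistent cells) compresses the global distance scale and destabilizes
   the density-based clustering that follows. The neighbor order 5 matches
   the locality used throughout the pipeline's design; the embedding is
   fully deterministic.
7. **Density-peak clustering** — in min-max-normalized coordinates, local
   density $\rho_i = \sum_j \exp(-(d_{ij}/d_c)^2)$ with $d_c$ the 2nd
   percentile of pairwise distances, separation $\delta_i$ = distance to
   the nearest denser point (the global maximum takes its largest
   distance), and the $k$ points of highest $\gamma = \rho\,\delta$ as
   centers. Non-center points join the center with the smallest
   shortest-path cost on a proximity graph keeping only edges shorter than
   0.1 (normalized units); the path constraint respects elongated,
   non-convex clusters. Points unreachable from every center fall back to
   the nearest center. All ties break deterministically by index.
8. **Cluster profiles** — per-cluster means of speed, directionality,
   arrest coefficient, displacement and path length, min-max normalized
   across clusters so each metric reads as "which cluster is highest /
   lowest"; metrics constant across clusters map to 0.5.

Default $k = 10$ suits exploratory phenotyping of real cohorts; validation
against the four synthetic archetypes uses $k = 4$.

## 3. Imaging quality

Movies are reduced to 2D by maximum-intensity projection over z and to
8 bits by `normalize_8bit()`, which linearly maps intensity so that the
top 1% of pixels saturate at 255 (percentile clipping stabilizes the
mapping against hot pixels). Five indices are computed:

- **Contrast (CR)** — $|\mathrm{Var}(\text{ref}) - \mathrm{Var}(\text{orig})| / \mathrm{Var}(\text{ref})$,
  where the reference is the movie contrast-stretched between its 1st and
  99th percentiles; near 0 when the movie already uses its dynamic range.
- **Noise (NR)** — PSNR (dB) of the movie against a 3×3 median-filtered
  copy (per frame, reflection borders); an identical filtered copy yields
  $\infty$.
- **Photobleaching (PB)** — the OLS slope of mean frame intensity against
  frame index; negative slopes indicate bleaching.
- **Saturation (SAT)** — fraction of 8-bit pixels in [245, 255].
- **Signal variation (SV)** — population coefficient of variation of the
  frame means, capturing flicker and drift-induced intensity swings.

Each index maps to a goodness in [0, 1] (CR: $1-\min(\mathrm{CR},1)$;
NR: $\min(\mathrm{PSNR}/50, 1)$ with 50 dB treated as transparent;
PB: one minus the fraction of initial intensity lost over the movie,
clamped; SAT: $1-\mathrm{SAT}$; SV: $1-\min(\mathrm{CV},1)$), and the
composite is their unweighted mean — the indices measure incommensurable
artifacts, so no data-independent weighting is defensible.

## 4. Depth recovery from 2D tracks

For a 2D-tracked point at time $t$, the frame is $t/\Delta t$ (validated
against the stack's frame interval), the pixel is the nearest-voxel
rounding of $(x, y)$, and the estimated slice is the argmax of intensity
across z at that pixel, ties resolved to the lowest slice. The estimate is
deliberately simple — no temporal smoothing or subpixel interpolation — so
its failure modes are transparent: it degrades when blobs overlap in the
same pixel column or when noise exceeds the axial intensity gradient.
Recovery quality is summarized by
$R^2 = 1 - \mathrm{SS}_{\mathrm{res}}/\mathrm{SS}_{\mathrm{tot}}$ against
ground-truth depth.

## 5. Synthetic ground truth

The generators are pure functions of their parameters and a seed (the
caller's RNG state is saved and restored), so every benchmark is exactly
reproducible. Archetypes:

- **directed** — constant step length with Gaussian turning noise;
  `persistence` is the expected per-step directional correlation
  $E[\cos\theta]$, realized by a wrapped-normal turn with
  $\sigma = \sqrt{-2\log(\text{persistence})}$. Default 0.99, calibrated
  so a 600 s track remains visibly directed (directionality
  0.90 ± 0.07) and the four archetypes are ≥95% linearly separable in
  (speed, directionality, arrest) space.
- **arrested** — i.i.d. isotropic Gaussian jitter around a fixed point.
  Default `jitter_sd` 0.1 µm: at 10 s sampling the instantaneous speed is
  Rayleigh with scale $6\sqrt{2}\,j$ µm/min, so $j = 0.1$ puts ≈92% of
  steps under the 2 µm/min arrest threshold — an unambiguously arrested
  phenotype. (At $j = 0.2$ only ~50% of steps are sub-threshold; that
  parameterization is *not* arrested under this model.)
- **brownian** — i.i.d. Gaussian steps with per-axis
  $\sigma = \bar\ell / \sqrt{\pi/2}$ so the mean step length matches the
  requested speed.
- **run_and_pause** — a two-state Markov chain alternating directed runs
  and arrested pauses with switching probabilities
  $1 - e^{-\text{rate}\,\Delta t}$, default rates 0.01/s.

Defaults (10 µm/min directed/run speed, 6 µm/min brownian, 600 s at 10 s)
are in the range reported for leukocytes in vivo.

The movie renderer draws each cell as a separable 3D Gaussian blob
(lateral SD 2 µm, axial SD 3 µm) on a constant background, with
multiplicative bleaching $(1-r)^{\text{frame}}$, uniform lateral drift,
additive Gaussian noise (clamped at 0), and optional intensity clipping to
emulate saturation. It does **not** model scattering, depth-dependent
attenuation, vignetting, motion blur, or Poisson photon statistics — it is
a testbed for the analysis code, not an optics simulator.
`gen_zrecovery_case()` places the true depth on the slice grid itself, so
noiseless recovery is exact by construction and any error is attributable
to noise; at SNR 5 (blob amplitude / noise SD) and 15 slices the median
$R^2$ over 20 movies is above 0.8.

## 6. Design decisions and problem sizes

- **MDS instead of a stochastic neighbor embedding.** The package uses
  deterministic classical MDS with local distance scaling. This preserves
  the between-archetype separation the clustering needs, makes results
  bit-reproducible without seed gymnastics, and avoids a heavyweight
  dependency; the cost is that very high-dimensional cluster geometry can
  be folded in 2D for much larger, messier cohorts than the sizes targeted
  here.
- **Rcpp kernels.** DTW and the 3×3 median filter are the only hot loops;
  both are implemented in C++ and cross-validated in the test suite
  against brute-force R oracles.
- **Graph assignment via igraph.** Shortest paths on the pruned proximity
  graph use `igraph::distances`; the tests validate against a
  Floyd–Warshall oracle on small inputs.
- **TIFF-only stack I/O**, with metadata (slice count, voxel size, frame
  interval) supplied by the caller since plain TIFF does not carry it
  reliably.
- **Problem sizes.** The pipeline is routinely exercised on 120 tracks ×
  57 windows × 4 features (distance matrix in well under a second) and
  movies of 30 × 15 × 64 × 64 voxels. Distance computation scales as
  $O(N^2 W^2)$; cohorts of a few thousand tracks remain practical, beyond
  which tracklet extraction (`extract_tracklets()`) bounds $W$.

## Limitations

Arrest-score windows saturate at $1/\varepsilon$ for perfectly frozen
cells, compressing differences among strongly arrested phenotypes. The
depth estimator assumes one dominant fluorophore blob per pixel column.
Quality goodness mappings use fixed, documented anchor points (50 dB PSNR,
full-loss bleaching) rather than dataset-calibrated ones, so composites are
comparable across movies but are not absolute quality probabilities.
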