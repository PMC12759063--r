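# ivtk — intravital track toolkit

`ivtk` is an R toolkit for quantitative analysis of leukocyte migration in
intravital two-photon microscopy. It covers the full path from raw cell
tracks and image stacks to interpretable motility phenotypes:

- **Track I/O** — read and write cell tracks in a native CSV schema, a
  TrackMate-style CSV dialect, and a JSON interchange format; resample,
  filter, fragment, subsample, and split tracks into tracklets.
- **Motility metrics** — speed, directionality (confinement/meandering
  ratio), arrest coefficient, square displacement, mean-squared displacement,
  velocity autocovariance, mean turning angle; per-video control
  normalization (residual speeds) and single-exponential decay fits of
  speed against sampling interval.
- **Imaging quality** — maximum-intensity projection, 8-bit normalization
  with percentile clipping, and five quality indices (contrast, noise/PSNR,
  photobleaching, saturation, signal variation) combined into a composite
  goodness score.
- **Depth recovery** — estimate the axial (z) position of 2D-tracked cells
  by locating the brightest slice along z at each tracked point, validated
  against ground truth by the coefficient of determination (R²).
- **Behavioral profiling** — sliding-window motility features, pooled
  z-scoring, multivariate dynamic time warping (DTW) distances (Rcpp), 2D
  embedding, density-peak clustering with shortest-path assignment, and
  min-max-normalized cluster profiles.
- **Synthetic ground truth** — seeded generators for four motility
  archetypes (directed, arrested, brownian, run-and-pause), 3D+time
  Gaussian-blob movies with configurable bleaching, drift, noise and
  saturation, and paired clean/artifacted movies for quality benchmarking.
- **CLI** — `ivtk_main()` plus an `exec/ivtk` wrapper exposing `metrics`,
  `profile`, `quality`, `zrecover`, and `simulate` subcommands with
  provenance JSON for every output.

## Scientific background

Immune cells imaged in vivo exhibit heterogeneous migration: T cells
alternate runs and pauses, neutrophils swarm directionally, and arrested
cells jitter in place. Summarizing a track by whole-track averages hides
this structure, so `ivtk` profiles behavior over time: each track is
linearly resampled to a 10 s interval, described by four features
(directionality, square displacement, mean speed, and an arrest score
`1/(MSD_w + ε)`) over 50 s sliding windows, and compared to other tracks by
dependent multivariate DTW. The resulting distance matrix is embedded in 2D
and clustered by density peaks (density ρ, separation δ, centers by
γ = ρ·δ, then shortest-path assignment on a pruned proximity graph).

Because imaging artifacts (photobleaching, noise, saturation, drift) bias
every downstream metric, the toolkit also scores movie quality, and because
many historical datasets were tracked in 2D projections, it recovers
approximate z-coordinates from the raw stacks: for each 2D point the pixel
column is scanned across slices and the brightest slice taken as the cell's
depth. On synthetic blob movies with signal-to-noise ratio 5 and ≥15
slices this recovers the true depth profile with median R² above 0.8.

## Worked example

```r
library(ivtk)

# A seeded synthetic run-and-pause track and its whole-track metrics
tr <- gen_track("run_and_pause", seed = 7, track_id = "demo")
tr
#> <ivtk_track demo> sim, run_and_pause, 61 points (2D), 600 s
track_speed(tr)            # 3.158 um/min
directionality(tr)         # 0.806
arrest_coefficient(tr, 2)  # 0.733

# Profile a labeled 120-track cohort (4 archetypes x 30) into k = 4 clusters
co  <- gen_cohort(n_per = 30, seed = 21)
res <- profile_pipeline(co$tracks, k = 4, seed = 42)
table(archetype = co$labels$archetype, cluster = res$clusters$label)
#>                cluster
#> archetype        1  2  3  4
#>   arrested      30  0  0  0
#>   brownian       0 30  0  0
#>   directed       0  0  6 24
#>   run_and_pause  0  0 30  0
round(res$profile$normalized, 2)
#>          speed directionality arrest_coefficient displacement path_length
#> cluster1  0.00           0.00               1.00         0.00        0.00
#> cluster2  0.99           0.15               0.03         0.16        0.99
#> cluster3  0.57           0.98               0.45         0.61        0.57
#> cluster4  1.00           1.00               0.00         1.00        1.00

# Imaging quality: a clean movie scores higher than its artifacted twin
pair <- gen_quality_pair(seed = 3)
quality_report(pair$clean)$composite       # 0.931
quality_report(pair$artifacted)$composite  # 0.814

# Depth recovery on a noisy single-blob movie with known z truth
case <- gen_zrecovery_case(seed = 1, snr = 5)
est  <- estimate_z(case$track2d, case$stack)
validate_z(est$z_um, case$truth_z_um)      # 0.739
```

The cluster profiles read off the planted biology: cluster 1 is the
arrested phenotype (maximal arrest, minimal everything else), cluster 2 is
brownian (fast but undirected), cluster 4 is directed (fast, maximally
straight), and cluster 3 captures run-and-pause (intermediate speed, high
directionality, intermediate arrest).

## Command-line interface

```sh
exec/ivtk metrics  --tracks cells.csv --dialect native_csv --out metrics.csv
exec/ivtk profile  --tracks cells.csv --k 4 --out clusters.csv
exec/ivtk quality  --stack movie.tiff --n-z 15 --out quality.json
exec/ivtk zrecover --tracks cells2d.csv --stack movie.tiff --n-z 15 --out tracks3d.csv
exec/ivtk simulate --preset four-archetypes --out cohort.csv
```

Flat `key=value` config files are supported via `--config`; explicit flags
override config values, and every output is accompanied by a provenance
JSON (package version, settings, input checksums).

## Limitations

- Stack file I/O is TIFF-only; HDF5 containers are not supported.
- The 2D embedding is classical multidimensional scaling with local
  distance scaling, not a stochastic neighbor method; it is deterministic
  by construction.
- The blob renderer models cells as Gaussian intensity blobs; it emulates
  bleaching, drift, noise and saturation but not scattering, vignetting or
  motion blur.
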