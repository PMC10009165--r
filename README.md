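# structmorph

Quantifies the spatial organization of filament-forming proteins — septins,
Cdc42 effector proteins, actin — in 16-bit fluorescence micrographs of
single cells, together with the cell-migration and actin-contractility
metrics used alongside such data.  It is written for cell biologists who
need per-image, per-class **area fractions** ("how much of the structure
area is dots vs. fragments vs. filaments/rings?") that can be compared
across perturbations such as Septin7 knockdown or forchlorfenuron
treatment.

## Method

For each image the pipeline computes

1. a cell mask: threshold, hole filling, morphological opening (disk,
   r = 7 px), area filter (≥ 5,000 px);
2. structures: local background subtraction (image − G_σ ∗ image, σ = 5 px),
   threshold (2,000 counts for septin, 1,500 for Cdc42ep1), 8-connected
   components inside the cell mask, inclusive area filter 10–400 px;
3. per object, 74 morphometric measures: ten region properties, neighbor
   distance and intensity statistics (mean, SD), and rotation-invariant
   Fourier descriptors — with the boundary resampled to 128 arc-length
   points and written as z(s) = x(s) + i·y(s),

   the features are |c_k| for k = ±1…±15 where c_k = (1/P) Σ_s z(s)·e^(−2πiks/P),

   plus 30 amplitudes |d_k|, k = 0…29, of the periodic nearest-neighbor
   distance profile along the boundary.  Objects whose truncated-series
   reconstruction errs by > 0.1 px on average are excluded;
4. classification: column z-scores → PCA keeping 90% of variance → DBSCAN
   (ε = 2, minPts = 3) → optional bimodality-driven refinement
   (b = (skew² + 1)/kurtosis, cutoff 5/9; 1-D Gaussian mixture or Otsu
   split) → merging of fine classes to three groups by co-alignment of
   their area-fraction loading vectors in the (PC1, PC2) plane;
5. per-image area fractions: fraction_k = Σ_{objects in class k} area /
   Σ_{classified objects} area, with the unclassified (noise) share
   reported separately.

Dynamics utilities implement mean per-step migration speed (µm/min),
directionality ratio (net displacement / path length), rose histograms of
net-displacement angles, relative stress-fiber length r(t) = L(t)/L(0) with
its least-squares shortening slope, focal-adhesion area and circularity
(4πA/P²), and whole-cell Pearson colocalization (no intensity threshold).

Because no imaging data are deposited with the original study, the package
ships a synthetic-microscopy generator with full ground truth (dots,
fragments, filament bundles, rings of 0.49–1.35 µm, aggregates over a
graded noisy background; persistent-random-walk trajectories; shortening
fibers; correlated image pairs).  The methods vignette
(`vignettes/structure-classification.Rmd`) documents every numerical choice
and what the synthetic world does and does not establish.

## Worked example

Classify six synthetic scenes drawn from three condition archetypes
(filament-rich, fragment-rich, ring-rich; scenes 1/4, 2/5, 3/6):

```r
library(structmorph)
arch <- list(c(dot = 150, fragment = 60, filament = 48, ring = 12),
             c(dot = 230, fragment = 140, filament = 12, ring = 9),
             c(dot = 120, fragment = 60, filament = 16, ring = 54))
set.seed(1)
scenes <- lapply(1:6, function(i) {
  cnt <- round(arch[[(i - 1) %% 3 + 1]] * runif(1, 0.7, 1.3) * runif(4, 0.85, 1.15))
  gen_structure_scene(scene_params(counts = cnt), seed = 1000 + i)
})
res <- run_classification(scenes)
res$profiles
#>   image_id noise_fraction undefined   class_1   class_2    class_3
#> 1        1     0.09405030     FALSE 0.5477319 0.3674114 0.08485669
#> 2        2     0.03872409     FALSE 0.8972240 0.0738541 0.02892189
#> 3        3     0.14972832     FALSE 0.4679290 0.1249704 0.40710059
#> 4        4     0.12693984     FALSE 0.6301178 0.3251448 0.04473737
#> 5        5     0.01483516     FALSE 0.8700502 0.0797546 0.05019520
#> 6        6     0.17593529     FALSE 0.5092025 0.1511656 0.33963190
```

Merged class 1 collects dots and fragments (small structures), class 2 the
filament bundles, class 3 the rings.  The filament-rich scenes (1, 4) show
the largest class-2 fractions, the ring-rich scenes (3, 6) the largest
class-3 fractions — the per-condition phenotype signature the pipeline is
designed to expose.  `noise_fraction` is the area share DBSCAN left
unclassified, reported separately and never folded into the fractions
(which sum to 1 over classified objects).

Migration metrics on simulated tracks (49 frames at 5-min intervals,
control-like mean speed 0.9 µm/min):

```r
tr <- gen_trajectories(walk_params(n_cells = 60, n_frames = 49, dt = 5,
                                   mean_speed = 0.9, persistence = 0.5, seed = 1))
dyn <- run_dynamics(tracks = tr)
mean(dyn$metrics$speed_um_min)          #> 0.8987072
mean(dyn$metrics$directionality_ratio)  #> 0.2744947
```

The speed estimator recovers the generating parameter to 0.1%; the
directionality ratio at persistence 0.5 over 4 h is far below 1, as
expected for a turning walk.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's main computation from scratch against the installed
package: it generates a six-scene archetype batch, executes the full
segmentation → features → PCA → DBSCAN → merge → area-fraction pipeline,
prints the resulting profiles, and exercises the trajectory, colocalization
and fiber-shortening quantifications, writing its report to `--out`.
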