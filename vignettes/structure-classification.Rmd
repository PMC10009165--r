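---
title: "Classifying septin and Cdc42ep1 structures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying septin and Cdc42ep1 structures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Septins polymerize into higher-order structures — diffraction-scale puncta,
short fragments, filaments that co-align with actin stress fibers, rings and
larger aggregates — and the balance between these forms shifts under
perturbations such as Septin7 knockdown or forchlorfenuron (FCF) treatment.
The same vocabulary applies to the Cdc42 effector Cdc42ep1, which decorates
septin structures and forms rings of 0.49–1.35 µm outer diameter under FCF.
`structmorph` turns a 16-bit fluorescence image of one cell into a per-image
**class profile**: the fraction of total structure area contributed by each
of a small number of interpretable structure classes.  Companion functions
quantify cell migration (speed, directionality ratio, rose histograms),
stress-fiber shortening, focal-adhesion morphometry and whole-cell Pearson
colocalization.

# Pipeline

The classification pipeline is, stage by stage:

1. **Cell mask** — threshold the raw image at a per-image, manually chosen
   intensity (`cell_threshold`; the original data used 12,000–24,000 counts
   for septin and 2,000–5,000 for Cdc42ep1), fill interior holes, open with
   a disk of radius 7 px, and drop components below 5,000 px.  An Otsu-based
   suggestion is attached for logging, but never applied automatically:
   threshold choice is deliberately manual.
2. **Local background subtraction** — subtract a Gaussian-smoothed copy of
   the image (σ = 5 px, reflective boundaries) and clamp negatives, so one
   structure threshold captures bright and dim structures alike.
3. **Structure segmentation** — 8-connected components of the
   background-subtracted image at `structure_threshold` (defaults 2,000 for
   septin, 1,500 for Cdc42ep1), restricted to the cell mask; components with
   more than half their pixels outside the mask are discarded, straddlers
   are clipped; areas outside the inclusive 10–400 px range are excluded.
4. **Features** — each object is described by 74 measures: ten region
   properties (Area, ConvexArea, Eccentricity, EquivDiameter, Extent,
   FilledArea, MajorAxisLength, MinorAxisLength, Perimeter, Solidity), the
   mean and SD of the boundary-to-nearest-neighbor distance and of the
   within-object intensity, 30 rotation-invariant Fourier amplitudes of the
   boundary treated as a complex signal, and 30 Fourier amplitudes of the
   periodic nearest-neighbor distance profile along the boundary.  Objects
   whose truncated-series boundary reconstruction errs by more than 0.1 px
   on average are flagged and excluded from clustering.
5. **Standardize, reduce, cluster** — column z-scores, PCA keeping the
   smallest set of components reaching 90% of variance, then DBSCAN with
   ε = 2 and minPts = 3 in the reduced space.  Unreachable points are noise
   (label −1).
6. **Optional refinement** — among the five classes with the largest mean
   object area, each class's most bimodal principal component is found via
   the bimodality coefficient b = (skewness² + 1)/kurtosis with cutoff 5/9;
   the two most populated such classes are split by a two-component 1-D
   Gaussian mixture, the rest by Otsu thresholding of the component values.
   This stage is off by default (it was needed for Cdc42ep1-type data, not
   septin).
7. **Merging and profiles** — fine classes are merged to three groups by
   average-linkage clustering of the cosine distance between their unit
   loading vectors in the (PC1, PC2) plane of the images × fine-classes
   area-fraction matrix; per-image area fractions are then reported over the
   merged classes, with the noise share reported separately.

```{r}
library(structmorph)
scenes <- lapply(1:3, function(i) gen_structure_scene(scene_params(), seed = i))
res <- run_classification(scenes)
res$profiles
```

# Tunable parameters

All tunables live in `pipeline_config()`.  The defaults are the published
values of the original analysis; the two thresholds are the only parameters
that were chosen per image in the original work.

| parameter | default | unit | meaning |
|---|---|---|---|
| `cell_threshold` | 12000 | counts | raw-image cell threshold (manual) |
| `structure_threshold` | 2000 | counts | structure threshold after background subtraction (1500 for Cdc42ep1-type channels) |
| `bg_sigma` | 5 | px | background smoothing σ |
| `open_radius` | 7 | px | opening disk radius for the cell mask |
| `min_cell_area` | 5000 | px | minimum cell component |
| `structure_area_range` | [10, 400] | px | inclusive object-area filter |
| `boundary_err_max` | 0.1 | px | Fourier reconstruction-error exclusion |
| `n_shape_modes`, `n_dist_modes` | 30, 30 | — | Fourier amplitudes kept |
| `pca_var_target` | 0.90 | — | cumulative explained-variance target |
| `dbscan_eps`, `dbscan_min_pts` | 2, 3 | — | DBSCAN in PCA space |
| `refine`, `refine_top_k` | FALSE, 5 | — | bimodality refinement stage |
| `merged_k` | 3 | — | number of merged classes |

# Numerical choices

* **Threshold semantics** are ≥ (inclusive) everywhere; the area filter is
  inclusive at both ends (a 400-px object is kept, a 401-px object is not).
* **Connectivity** is 8 for objects and 4 for background, the convention
  that makes outer-boundary tracing consistent; boundaries are traced with
  Moore's algorithm and oriented counter-clockwise (in x = col, y = −row
  coordinates); holes contribute no boundary.
* **Boundary resampling.** All Fourier descriptors are computed on the
  boundary resampled to 128 arc-length-uniform points.  The traversal is
  anchored at the vertex farthest from the boundary centroid, with exact
  ties broken by the lexicographically largest centroid-distance sequence;
  this makes the sampling — and hence the amplitudes — exactly invariant
  under 90°/180° rotations of the pixel set, not merely up to resampling
  error.
* **Complex signal convention** is z = col − i·row, so the counter-clockwise
  boundary of a disk of radius r has |c₁| = r and all other amplitudes ≈ 0.
* **Ellipse moments** use the standard +1/12 per-pixel variance correction,
  so a single pixel has MajorAxis = MinorAxis = 4·(1/12)^0.5 and
  eccentricity 0.
* **Perimeter** is the raw length of the traced boundary polygon; its
  digitization bias (≈ 5–8% over smooth shapes) is accepted and documented.
  Focal-adhesion **circularity** (4πA/P²), by contrast, uses a 16-mode
  Fourier low-pass smoothed contour for P, because the staircase bias would
  otherwise depress a perfect disk to ≈ 0.89; values are capped at 1.05
  (the declared digitization tolerance).
* **DBSCAN border points** are assigned to the cluster of their nearest
  core point.  Classic DBSCAN leaves shared border points to visit order;
  the nearest-core rule makes the partition invariant to permutations of
  the input, which the test suite asserts against a brute-force
  density-reachability closure.
* **Lone objects** (no neighbor in the frame) receive the image diagonal as
  their sentinel neighbor distance, with a constant distance profile, and
  are flagged.
* **Zero-variance feature columns** are dropped with a warning before
  standardization (symmetric shapes genuinely produce exactly-zero even
  Fourier modes).
* **Monotonicity caveat.** Raising the structure threshold cannot add
  foreground pixels, and for isolated single-peak structures it cannot add
  objects; but a noisy plateau or two overlapping peaks can split into
  several components as the threshold rises, so object *counts* are not
  monotone in general.

# The synthetic world

No microscopy data are deposited with the original study, so validation
rests on `gen_structure_scene()`: one elliptical cell plateau over a graded
background (offset drawn from the 12,000–24,000 count manual-threshold
regime), structures drawn inside it, then Poisson shot noise (gain 2),
Gaussian read noise (σ = 60 counts) and 16-bit quantization.  Defaults are
0.1 µm/px and ~300 objects per 512² scene.  Trajectories come from a
persistent random walk (uniform turning angles of half-width π(1−p)); fiber
traces from linear shortening plus Gaussian noise; colocalization pairs
from a bivariate Gaussian pixel model.

The structure classes are deliberately **stylized**:

* dots are monodisperse disks of radius 2 px (diffraction-spot scale);
* fragments are straight 8 × 2 px rods sharing the filament orientation
  (they model broken bundle pieces);
* filaments are straight 15 × 3 px rods in parallel bundles of four at 6-px
  spacing, all bundles sharing one orientation per scene — as septin
  filaments co-align with stress fibers in directionally migrating cells;
* rings are drawn from six discrete outer diameters spanning the published
  0.49–1.35 µm range, placed as axis-aligned pairs inside an exclusion halo
  sized so that each ring's nearest neighbor is always its sibling;
* aggregates are irregular star-shaped blobs (radius 5–8 px).

Two design facts force this stylization, and both are properties of the
published method, not of the generator:

1. **The 0.1-px exclusion rule caps elongation.**  A truncated 30-mode
   Fourier series cannot follow the pixel staircase of a thin object whose
   boundary exceeds roughly 45 px at oblique orientations, so such objects
   are excluded by the published rule itself (verified against an
   independent NumPy implementation to nine decimals).  Filaments much
   longer than ~2 µm at 0.1 µm/px therefore cannot be *classified* at all —
   the generator's filament length respects that resolving power, and the
   default scenes keep the excluded fraction below 1%.
2. **ε = 2 requires stereotyped objects.**  After z-scoring, every feature
   contributes unit variance, and the ~30 distance-profile amplitudes act
   as independent environment-noise dimensions.  At desk scale (thousands,
   not tens of thousands, of objects) DBSCAN with ε = 2 and minPts = 3 only
   forms clusters where digitized shapes *and* neighbor environments recur
   almost exactly.  Monodisperse geometry, shared orientations, bundles and
   halos are what give each class recurring exemplars.  Widening the
   geometry ranges (all knobs are exposed) degrades classification smoothly
   toward noise — which is itself informative about the method's operating
   envelope.

Consequently, a green end-to-end test establishes that the pipeline
recovers known, well-separated class mixtures on its stated world.  It does
**not** establish robustness to continuous morphology gradients, touching
structures, uneven focus, photobleaching or multi-cell fields; none of
those are modeled.

The end-to-end validation batch mirrors the original study's experimental
design rather than drawing class counts independently: scenes come from
three condition archetypes (filament-rich "control", fragment/punctum-rich
"knockdown", ring-rich "inhibitor").  Class merging by co-alignment of
area-fraction loadings is only identifiable when mixtures co-vary in a
structured way — with independent counts the 2-PC loading directions of the
fine classes are essentially noise.

# Open design decisions

Where the original description is silent, this package decides and
documents:

* bimodality statistic and cutoff: b = (skewness²+1)/kurtosis, 5/9;
* "simple thresholding of the selected PC value": Otsu's threshold;
* 1-D GMM: two components, ten restarts, fixed seed, posterior argmax;
* co-alignment merge: cosine distance between unit (PC1, PC2) loading
  vectors, average linkage (the original rule is illustrated only in an
  unavailable supplement; this is a declared substitute);
* the count discrepancy — the original text says "72 measures" but names
  ten region properties plus 4 + 30 + 30 others — is resolved by keeping
  all ten named properties (74 features, configurable);
* intensity statistics are measured on the background-subtracted image
  (the segmentation substrate);
* speed is the mean per-step displacement over dt, not net displacement
  over total time; the track filter keeps tracks of strictly more than
  5 frames;
* images are read and written as 16-bit binary PGM (no TIFF reader exists
  in the target environment); label maps and tables round-trip exactly.

# Limitations

Single cell per frame (no instance separation of touching cells); 2-D only;
no optical PSF simulation; no gap-closing in track linking; descriptive
statistics only (no hypothesis testing); and the synthetic world's
idealizations listed above.
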