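---
title: "Delineating biophysical seascape regions with batch self-organizing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating biophysical seascape regions with batch self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seascaper)
```

## The problem

Marine spatial planning needs a partition of a seascape into regions of
similar environmental conditions — bioregions that act as proxies for habitat
types and ecosystem function where direct biological surveys are sparse.
`seascaper` implements such a delineation for a tropical seascape (the
reference region is the Sunda Banda Seascape, 113–135°E, 0–13°S) from six
per-pixel biophysical variables derived from gridded ocean fields:

| variable | meaning | units |
|---|---|---|
| `avg_sst` | long-term mean sea surface temperature | °C |
| `max_sst` | warmest monthly climatological SST | °C |
| `min_sst` | coolest monthly climatological SST | °C |
| `chla` | long-term mean chlorophyll a | mg/m³ |
| `currents` | long-term mean current speed | m/s |
| `salinity` | long-term mean salinity | PSU |

The pipeline is: derive climatological variables from monthly/daily stacks →
regrid coarse model fields to the fine satellite grid → mask land → screen
collinearity → range-standardize → cluster pixels with a batch
self-organizing map (SOM) over a scan of lattice topologies → select the
partition maximizing the mean silhouette index → characterize the classes.

Because the multi-year satellite and model inputs are not shipped, the
package contains a first-class synthetic-data module that generates seeded
inputs with the statistical structure the analysis assumes, so the entire
pipeline runs and is tested offline.

## Variable derivation

`longterm_mean()` averages a pixel over all time steps where it is valid. A
pixel must be valid in at least half the steps (configurable `min_frac`),
otherwise it is dropped: means over sparse, cloud-gapped series are biased
toward the seasons that happen to be observed. The same rule applies within
each calendar month in `monthly_climatology()`; `climatology_extremes()`
then takes the per-pixel max and min over the twelve monthly grids, and
declares a pixel invalid if *any* month is missing, since an extreme over a
partial year is not comparable. Current speed is averaged per time step
(speed of the daily field, then the mean), not as the magnitude of the mean
vector — the two differ wherever flow reverses seasonally.

## Regridding and standardization

Coarse model fields (the current/salinity analogues) are brought onto the
fine grid by separable cubic-convolution interpolation
(`resample_bicubic()`, kernel parameter `a = -0.5`, the Catmull–Rom choice —
the most common "bicubic" definition; exact on constant and linear fields).
Nodata must not bleed through the 4×4 support near coastlines, so invalid
source cells are pre-filled with their nearest valid value and the result is
re-masked with the target-resolution land mask.

Collinearity is screened (`assess_collinearity()`, Pearson |r| ≥ 0.85
flags a warning) but variables are never dropped automatically. Each
variable is then mapped to [0, 1] by its observed range over the cropped,
masked study region (`range_standardize()`), so all six contribute equally
to the feature-space distances; min/max are retained for the inverse map.
Standardization is applied last (after cropping and masking) so the unit
interval reflects the study region only.

## The batch SOM

Neurons live on an `x × y` hexagonal lattice (odd rows offset; interior
neurons have six neighbors; `1 × k` degenerates to a path, the *linear*
topology). The neighborhood metric is the link distance: the minimum number
of lattice hops between neurons.

Training (`train_batch()`) is batch, not online, and deterministic given the
initialization. Each step assigns every pixel to its best-matching unit
(BMU; Euclidean distance in the standardized feature space, ties to the
lowest neuron index) and replaces each neuron's weight by the mean of all
pixels whose BMU lies within link distance `r(t)` (a hard-indicator
neighborhood, the natural companion of batch means over an integer metric).
Defaults are 1000 steps and initial radius 3. The radius decays linearly
from 3 to 1 over the first 90% of steps (the ordering phase) and is 0 for
the final 10%: with radius 0 the update is exactly Lloyd's k-means
iteration, so the final partition is a clean Voronoi partition — which is
what silhouette evaluation assumes. Training stops early once the largest
weight change in the radius-0 phase falls below `tol = 1e-9`.

Two practical guards matter on small lattices:

* the effective radius is capped one hop below the lattice diameter: a
  neighborhood spanning the whole lattice carries no topological information
  and irreversibly collapses every neuron to the global mean;
* since the hard-indicator neighborhood only changes when the radius crosses
  an integer, converged stretches within a radius regime are skipped — a
  pure speed-up with identical results.

Initialization defaults to the deterministic `pca_plane`: neurons laid out
on the plane of the first two principal directions, spanning the mean ± 2 SD
along each (clamped to the data box). `sample` (k random data rows) and
`random` (uniform in the data box) are available, seeded.

### Multi-start fitting in the scan

Batch SOM training is a deterministic descent, and on data with many
well-separated clusters a single run regularly stalls in a split-and-merge
local optimum (one true cluster split across two neurons while two others
share one). The topology scan therefore trains each scenario from the
deterministic initialization plus `restarts` (default 4) seeded `sample`
initializations, and keeps the fit
with the lowest quantization error — the mean distance of pixels to their
BMU, i.e. the objective the radius-0 phase descends. The restart pick never
looks at the silhouette index that subsequently ranks scenarios, so model
fitting and model selection remain separate criteria.

## Scenario scan and selection

`enumerate_scenarios(4, 25)` lists every unordered lattice shape `{x, y}`
with `x·y = k` for `k = 4..25`, including the linear `1 × k` — 43 scenarios
in total. Each is trained, every pixel labeled, and the partition scored by
the mean silhouette index

$$SI_i = \frac{b_i - a_i}{\max(a_i, b_i)},$$

where $a_i$ is the mean distance from pixel $i$ to the other pixels of its
cluster and $b_i$ the smallest mean distance to the pixels of another
cluster; $SI_i \in [-1, 1]$, singletons score 0. The scenario with the
largest mean SI wins; ties break toward fewer clusters, then the more linear
topology. A scenario whose map collapses below two non-empty classes is
recorded at mean SI −1 and flagged rather than aborting the scan.

The exact silhouette is O(n²); for large tables it is evaluated on a seeded
uniform subsample (default 10 000 pixels, distances within the subsample).
The implementation is checked against a literal brute-force oracle to 1e-12
and against an independent library implementation.

## The synthetic seascape

`synth_seascape()` emulates the structure the analysis assumes, not the
physics of any real sea:

* a blob-like land mask from thresholded smoothed noise (default land
  fraction 0.2);
* `K = 9` planted regimes: seed cells drawn uniformly among sea cells, every
  sea cell labeled by its nearest seed — contiguous, irregular Voronoi
  provinces;
* distinct six-variable signatures per regime: each variable gets K evenly
  spaced levels across a realistic tropical range, permuted independently
  per variable; among 200 seeded permutation draws the one maximizing the
  smallest pairwise signature distance is kept, so identifiability of the
  planted structure never hinges on one near-duplicate pair of regimes.
  Max/Min SST are placed symmetrically about Avg SST through a per-class
  seasonal amplitude (0.9–2.0 °C), which a sinusoidal seasonal cycle then
  reproduces exactly;
* within-regime variability as spatially smoothed Gaussian noise
  (correlation length 2 cells), with per-variable SD set to 1/5 of the
  smallest between-class gap — the strong-separation regime the recovery
  analyses assume. Chlorophyll noise acts on the log scale (then
  exponentiated with the lognormal mean correction), keeping the field
  positive and right-skewed as observed chlorophyll is;
* 11 years of monthly SST-like data (`avg ± amplitude·sin(2π(m−1)/12)` plus
  0.3 °C monthly noise) and about five years of coarse current/salinity-like
  stacks at 1/3 the fine resolution, exercising the regridding step.

The default problem size for recovery analyses is a 60 × 60 grid (≈ 2900 sea
pixels), which keeps a full 43-scenario scan with restarts around a minute;
the statistical structure, not the pixel count, is what the analyses probe.

What the generator does *not* emulate: real cloud-gap missingness patterns,
advective anisotropy, fronts or gradual gradients between provinces, and
inter-variable correlations within a regime. Passing recovery tests
therefore show that the pipeline identifies well-separated contiguous
regimes; they do not certify performance on gradual real-world transitions.

## Characterization

`class_summary()` reports, per class, the percentage of classified sea
pixels inside an area-of-interest mask and the mean ± SD of each variable in
raw units. SDs are population SDs (divide by n): the classified pixel set is
the full population of interest, not a sample (a `sample` option exists).
Percentages use only in-area pixels — a class entirely outside the area
scores 0% while still being profiled — and sum to 100 over in-area classes.
`summary_ranges()` gives per-variable min/max/spread of class means over any
class subset. Class numbers are lattice indices of the selected model and
are arbitrary up to permutation; all comparisons against external summaries
must be permutation-invariant.

A reference nine-class summary of the Sunda Banda Seascape
(`sbs_reference_summary()`) ships as a plain-text fixture to exercise this
arithmetic on real printed values.

## Numerical choices and degenerate inputs

* Tie-breaks: BMU ties and coincident-seed ties go to the lowest index;
  selection ties to smaller k, then smaller x. All deterministic.
* Missing data: the 50% coverage rule above; a feature-table row is dropped
  if any of the six variables is invalid at that pixel.
* A constant variable aborts range standardization (degenerate input), and
  an all-identical table collapses every scenario, which the scan flags.
* Cropping keeps cells whose centers fall in a half-open box `[min, max)`,
  so adjacent crops never double-count an edge cell.
* On-disk rasters use a single nodata sentinel; the in-memory mask is
  authoritative. Grids are written as Arc/Info ASCII text with 17
  significant digits, so float round-trips are value-exact.
* All random draws (masks, regimes, noise, subsamples, restarts) are seeded
  and bit-reproducible; generators save and restore the caller's RNG state.

## Known limitations

* "Bicubic" is implemented as cubic convolution with `a = -0.5`; other
  conventions (B-spline bicubic, `a = -0.75`) differ in the third decimal on
  smooth fields.
* The silhouette subsample makes scenario scores stochastic under different
  subsample seeds for very large tables; the default evaluates all pixels
  whenever `n ≤ 10000`.
* Silhouette selection resolves cluster counts only as well as the fitted
  partitions allow; even with multi-start fitting, a scan on weakly
  separated regimes can prefer k one below or above the planted count, with
  the extra or missing class being a split or merge of the two most similar
  regimes.
* Only plate carrée lat/lon grids are supported; there is no reprojection,
  and no download client for the real satellite/model inputs.
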