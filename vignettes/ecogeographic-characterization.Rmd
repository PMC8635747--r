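---
title: "Ecogeographic characterization: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecogeographic characterization: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogeo)
```

## The problem

Collections of wild crop relatives are documented as *accessions*:
georeferenced records of where a plant of a given species was found.
Characterizing the climate and soil at those places answers two questions
breeders and conservationists care about: *what environmental envelope
does each species occupy* (its ecological descriptors), and *where is the
diversity concentrated* (hot spots worth conserving or collecting). This
package implements that workflow for point occurrences plus gridded
environmental layers, together with the multivariate analysis that links
the climate and soil blocks.

## Occurrence cleaning

Raw occurrence databases are noisy: the same collection appears in several
repositories, coordinates are rounded to whole degrees or minutes, and
some records are georeferenced to places where the species cannot grow.
`clean_occurrences()` applies four rules in a fixed order — duplicates,
precision, nodata, altitude — so that each dropped record is attributed to
exactly one rule and the report always reconciles with the input count.

* **Duplicates** are exact matches of species and string-normalized
  coordinates. A distance-based tolerance would be order-dependent and
  would need an arbitrary radius; exact matching is deterministic and
  captures what repository mirroring actually produces.
* **Precision** is measured as decimal digits of the written coordinate.
  The default floor of 2 decimals (~1.1 km at the equator) matches the
  ~900 m resolution typical of the environmental layers: a coarser
  coordinate cannot be meaningfully assigned to a cell. The threshold is a
  declared default, not an estimate, and is configurable.
* **Altitude** operationalizes "atypical data": a record whose grid
  elevation falls outside its species' elevational envelope is treated as
  a georeferencing error. Envelopes for the 16 wild-tomato-group taxa ship
  as editable defaults (`default_altitude_ranges()`).

Cleaning is idempotent — a second pass drops nothing — which the test
suite asserts on generated data.

## Grids and extraction

`raster_grid` is a minimal in-memory raster: a matrix with a northwest
corner, a square cell size in degrees, and `NA` for nodata. Cell (1,1) is
the northwest cell and rows grow southward; this convention is stated
explicitly because row-order ambiguity is the classic source of silent
bugs when exchanging grids between tools. Files are read and written as
ESRI ASCII grids, a plain-text format whose write–read round trip is
bit-exact here (values are printed with `%.17g`, which round-trips IEEE
doubles). No GDAL-backed reader is bundled, so binary raster formats are
rejected with an informative error rather than half-supported.

Extraction is point-in-pixel with no interpolation, under half-open
intervals: `[west, west + cell)` in longitude and `(north − cell, north]`
in latitude. Nearest-cell sampling is used for continuous and categorical
layers alike — bilinear interpolation would be meaningless for class codes
and would blur the continuous layers' provenance; point-in-pixel is also
what desktop GIS extraction does by default. Out-of-extent and nodata
points yield missing values, never errors. Rows of the environmental
matrix with any missing value are excluded from the downstream statistics
(complete-case) and logged; descriptors, by contrast, use per-cell
complete cases, since each species × variable summary is independent.

## Collinearity screen

With ~35 candidate variables, near-duplicates (e.g. precipitation of the
wettest month vs. wettest quarter) destabilize any subsequent multivariate
analysis. The screen computes the Pearson matrix and then greedily: while
any retained pair has |r| above the threshold (default 0.90), take the
worst pair and eliminate one member. The member *conserved* is the one
with more |r| > threshold partners among retained variables — the "hub"
that can stand in for the most others — with ties broken by the larger sum
of |r| and then by input column order. Every step is logged with the tie
flags, and `rule = "drop_hub"` inverts the retention choice, so the
sensitivity of the retained set to this convention is a one-flag check.
The procedure is deterministic given column order.

## Canonical correlation analysis

The climate block X (n × p) and soil block Y (n × q) are standardized and
the analysis is correlation-based (covariance-based CCA would let
large-variance variables such as annual precipitation dominate). The
canonical correlations and weights come from the SVD of
`Rxx^(−1/2) Rxy Ryy^(−1/2)`, with symmetric inverse square roots by
eigendecomposition under a 1e−10 eigenvalue floor. A numerically singular
block is an error that advises a small `ridge`, which is then added to the
block correlation diagonals only — regularization is never silent.

Reported alongside the correlations:

* **eigenvalue proportions**: λ_k = r_k²/(1−r_k²), expressed as
  percentages of Σλ. This is the "percent of variation" convention
  attached to successive canonical pairs in classical outputs; the
  package documents it as an eigenvalue share, not a variance
  decomposition of the raw data.
* **sequential Bartlett tests**: Λ_k = Π_{i≥k}(1−r_i²), chi-square
  −(n−1−(p+q+1)/2)·lnΛ_k on (p−k+1)(q−k+1) degrees of freedom. The
  chi-square approximation was chosen over Rao's F for its simplicity and
  because the two agree at the sample sizes this workflow targets
  (thousands of accessions); its finite-sample behaviour is verified
  empirically in the test suite (type-I error at n = 200 inside the exact
  binomial 99% envelope over 500 replicates).
* **loadings and cross-loadings**: correlations of each original variable
  with its own and the opposite block's canonical scores. In-sample these
  satisfy cross(v, k) = r_k · loading(v, k) exactly, which the tests
  assert to 1e−10.

Signs of canonical variates are arbitrary; to make outputs reproducible
across platforms, each climate variate is oriented so its largest-|loading|
variable loads positively, and each soil variate is then oriented so the
canonical pair correlates positively. Anchoring both blocks independently
would have allowed negative realized pair correlations and broken the
cross-loading identity above, which is why the second block follows the
first.

## Ecological descriptors

For each species × variable cell: n, min, max, quartiles, and the
quartile coefficient of variation CV = (Q/Med)·100 with Q = (Q3−Q1)/2.
This robust CV (rather than sd/mean) is the convention in ecogeographic
characterization because environmental samples at occurrence sites are
skewed and outlier-prone. Quartiles default to linear interpolation at
0.25/0.5/0.75·(n−1) (sample-quantile type 7, R's default); the estimator
is configurable and recorded in the output metadata since published
tables rarely state which rule produced them. When the median is zero —
routine for the precipitation of the driest month in desert species — CV
is reported as 0 with a `zero_median` flag rather than infinity, matching
how such cells are printed in published tables; the flag keeps the
convention auditable.

## Edaphoclimatic diversity

Categorical layers (Köppen–Geiger climate types, FAO soil units) are
sampled at the accession points and tabulated as counts and within-row
percentages per species or per phylogenetic group, plus richness (classes
with nonzero count). The full 30-code climate and 28-code soil
vocabularies ship as constants; codes missing from a supplied dictionary
are tolerated as `UNKNOWN_<code>` with a warning because synthetic or
regional layers legitimately use subsets. Group tables are exactly the
species tables aggregated through the species → group map, which is
asserted as an invariant.

## Hot spots

Accessions are first aggregated into density bins: points are projected
onto a local azimuthal-equidistant plane anchored at their centroid
(geodesic distance and bearing on the WGS84 ellipsoid via `geosphere`)
and snapped to a fixed 1-km square grid. Deterministic grid binning was
chosen over order-dependent agglomerative grouping: the result depends
only on the point set. Each occupied bin then receives the local
Getis–Ord Gi* z-value in its variance-corrected form with the focal bin
included in its own neighborhood, using binary distance-band weights. The
band distance is not something occurrence data can dictate; the default
of 50 km is of the order of desktop-GIS defaults for study areas this
size, is configurable, and is recorded in output metadata. Classes follow
the conventional |z| thresholds 1.65/1.96/2.58. No multiplicity
correction is applied to the z map by default, mirroring how such maps
are conventionally reported; the per-bin p-values are exported so any
correction can be applied downstream. Bin values are accession counts by
default; per-bin species richness is available via `value = "richness"`.

## The synthetic study system

The generator exists so that every stage can be tested against *known
truth*, not plausibility:

* `planted_cca_sample()` builds paired blocks whose population canonical
  correlations are exactly the requested ρ (shared latents plus noise,
  then fixed invertible within-block mixing, to which CCA is invariant).
* `synthetic_landscape()` builds one grid per variable as
  `center + scale·(β·H + γ·G_i + σ·ε)`: a shared smooth "humidity" field
  H plants the climate–soil structure, layer-specific smooth fields G_i
  and white noise provide realistic nuisance variation, and an exact
  monotone 0–4,000 m altitude ramp supports the cleaning rules. The
  planted canonical spectrum is computed exactly from the cell-wise
  covariance of the deterministic parts plus the noise variances — the
  population a uniform sampling of cells would see. With the default
  β = 1, γ = 1.2, σ = 1 the leading planted correlation lands near 0.8,
  the order of magnitude reported for real climate–soil systems.
* `synthetic_occurrences()` disperses 200 accessions per species (~3,200
  in total, the scale of a curated continental collection) around niche
  centres placed so each species sits mid-envelope on the altitude ramp,
  then plants exactly accountable defects: 10 duplicates, 5 low-precision
  records, 5 out-of-altitude records. The cleaning report must recover
  these counts exactly, and the tests require it.
* `categorical_layer()` thresholds a smooth field at rank quotas so class
  cell proportions are exact, enabling multinomial-envelope recovery
  tests.

Everything is a pure function of (configuration, seed). The default study
window is a 10° × 10° block of western South America at 0.05° cells
(200 × 200) — realistic coordinates, small enough that the full pipeline
runs in seconds.

What the synthetic system does **not** emulate: spatial autocorrelation
of the noise, non-Gaussian and bounded variables (a synthetic pH can
stray outside [0, 14]), sampling bias along roads and rivers, and
taxonomic misidentification. Passing tests therefore demonstrate the
correctness of the algorithms under known structure, not robustness to
every pathology of real collections.

## Numerical conventions

* Eigenvalue floor 1e−10 in the inverse square roots; ridge only on
  explicit request.
* Zero global variance in Gi* defines all z = 0 (a uniform map has no
  hot spots) instead of dividing by zero.
* Quartile estimator type recorded with descriptor outputs; the CV of a
  negative-median cell uses |Med| so CV stays nonnegative.
* All JSON/CSV artifacts are written without timestamps, so identical
  configurations reproduce byte-identical outputs (asserted in the test
  suite, manifest checksums included).

## Known limitations

* Only the ESRI ASCII grid format is supported for rasters; inputs in
  binary formats must be converted first.
* Coordinates are assumed WGS84 decimal degrees; no reprojection.
* Complete-case handling of missing environmental values can bias the
  CCA sample if missingness is spatially structured; the dropped-row log
  exists so users can check.
* The Bartlett chi-square is asymptotic; at small n with many variables
  its p-values should be read cautiously (the package warns when
  n ≤ p + q).
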