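# ecogeo

Ecogeographic characterization of georeferenced plant genetic resources.

`ecogeo` is an R package for the workflow used to characterize wild-species
accessions (for example the wild relatives of tomato in western South
America) by the climate and soil of the places where they occur. Given an
occurrence table (species, longitude, latitude) and a stack of gridded
environmental layers, it:

1. **cleans** the occurrences — exact duplicates, coordinates with too few
   decimal digits, records off the grid, and records whose altitude falls
   outside the species' elevational envelope are dropped, with a full
   audit report;
2. **extracts** the value of every layer at every accession
   (point-in-pixel, no interpolation) into an accessions × variables
   matrix;
3. **screens collinearity**: Pearson correlations are computed and, while
   any pair has |r| > 0.90, one member of the worst pair is eliminated
   (the variable with more high-correlation partners is conserved), with
   a step-by-step elimination log;
4. runs a **canonical correlation analysis** between the climate block and
   the soil block: canonical correlations r_k from the SVD of
   `Rxx^(-1/2) Rxy Ryy^(-1/2)`, eigenvalues λ_k = r_k²/(1−r_k²) and their
   percentage shares λ_k/Σλ, coefficients, loadings, cross-loadings, and
   sequential Bartlett chi-square tests
   (−(n−1−(p+q+1)/2)·ln Λ_k with Λ_k = Π_{i≥k}(1−r_i²));
5. computes per-species **ecological descriptors** — min, max, median, and
   the quartile coefficient of variation CV = (Q/Med)·100 with
   Q = (Q3−Q1)/2;
6. tabulates **edaphoclimatic diversity** — counts, within-species
   percentages and richness of Köppen–Geiger climate types and FAO soil
   units sampled from categorical layers;
7. detects **hot spots**: accessions are aggregated into 1-km density bins
   (local azimuthal-equidistant projection), and each bin gets a local
   Getis–Ord Gi* z-value over a 50-km neighborhood band, classified at
   |z| > 1.65 / 1.96 / 2.58.

A synthetic-data module generates every input with known ground truth —
planted canonical correlations, planted cleaning defects, planted class
proportions — so the whole pipeline is testable end to end without any
external download.

## Worked example

```r
library(ecogeo)

cfg <- pipeline_config(out_dir = "demo_run", seed = 7)
run_pipeline(cfg)
#> [simulate] records=3220 rasters=21
#> [clean] input=3220 kept=3200
#> [extract] rows=3200 dropped=0
#> [screen] retained=19 eliminated=0
#> [cca] pairs=8
#> [descriptors] cells=304
#> [diversity] climate_classes=12 soil_classes=17
#> [hotspot] bins=3183 hot99=190 cold99=0

read.csv("demo_run/cca_summary.csv")[1:3, 1:4]
#>   k       cor eigenvalue proportion_pct
#> 1 1 0.9234934  5.7953307      68.789778
#> 2 2 0.7292498  1.1358636      13.482545
#> 3 3 0.6522604  0.7404734       8.789318
```

Reading the output: 3,220 simulated records are reduced to 3,200 by the
cleaning rules (the 20 dropped are exactly the planted defects, as
`cleaning_report.json` shows). None of the 19 layers exceed the 0.90
collinearity threshold here, so all are retained; the CCA then finds a
leading climate–soil canonical correlation of 0.923 carrying 68.8% of the
eigenvalue total — close to the planted population value 0.919 recorded in
`truth.json`. The diversity stage recovers all 12 planted climate types
and 17 soil units, and the hot-spot stage flags the densest 1-km bins at
the 99% level.

Each stage reads and writes only files under `out_dir`, so any stage can
be re-run alone (`run_pipeline(cfg, stages = "cca")`). A thin command-line
wrapper with the same stages as subcommands is installed at
`system.file("cli", "ecogeo.R", package = "ecogeo")`.

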