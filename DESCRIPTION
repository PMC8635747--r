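Package: ecogeo
Title: Ecogeographic Characterization of Georeferenced Plant Genetic Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ecogeographic characterization of georeferenced
    wild-species accessions, as used in plant genetic-resource studies:
    reading and cleaning occurrence tables, point extraction of
    edaphoclimatic variables from gridded layers (ESRI ASCII grids),
    collinearity screening of the variable set, canonical correlation
    analysis between climate and soil blocks with eigenvalue proportions
    and sequential Bartlett tests, per-species ecological descriptors
    based on a quartile coefficient of variation, frequency tables of
    categorical climate types and soil units, and hot-spot detection with
    the local Getis-Ord Gi* statistic on kilometre-scale density bins.
    A synthetic-data generator with known ground truth (planted canonical
    correlations, planted cleaning defects, planted class proportions)
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
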