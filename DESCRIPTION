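Package: speciogeo
Title: Geographic Variation in Tip Speciation Rates on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to map and explain geographic variation in speciation
    rates estimated at the tips of time-calibrated phylogenies. Computes
    inverse equal-splits tip rates (the DR statistic) aggregated over a
    posterior sample of trees, grids species ranges into presence-absence
    assemblages with per-cell rate summaries, tests for binary
    state-dependent speciation with a nonparametric trait-simulation null,
    fits maximum-likelihood spatial-error regressions with distance-band
    inverse-distance weights and Nagelkerke pseudo-R-squared, and derives
    bioregion-level ecological predictors (climate-change velocity, terrain
    roughness, net relatedness index) for multi-predictor driver models. A
    synthetic-world generator produces trees, traits, gridded ranges,
    climate and elevation rasters, and bioregion partitions with known
    planted structure so the whole pipeline can be exercised and calibrated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
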