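Package: altiband
Title: Altitudinal Banding, Area Correction and Spatial Analysis of
    Elevational Diversity Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing elevational gradients of taxon richness on
    mountain checklists. Builds equal-elevation and equal-area altitudinal
    band schemes from a digital elevation model, interpolates species
    elevational ranges into per-band richness for taxonomic, life-form and
    range-size groups, corrects richness for the species-area effect either
    by a fitted power law or by equal-area banding, simulates a mid-domain
    effect null model with a closed-form expectation, and compares the two
    area-correction methods with polynomial regressions, Moran's I
    correlograms and simultaneous autoregressive error models selected by
    small-sample AICc. Includes a synthetic mountain and checklist generator
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
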