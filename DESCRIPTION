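Package: envelopeshift
Title: Climate-Envelope Projections of Tree Species Under Ocean-Circulation
    Collapse Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for projecting tree-species
    distributions from monthly climate grids: statistical change-factor
    downscaling, empirical quantile mapping of climate-model series,
    superimposition of AMOC-collapse temperature and precipitation anomalies,
    derivation of bioclimatic variables (Thornthwaite potential
    evapotranspiration and climatic water balance aggregates), climate-envelope
    models built from conflated per-variable probability densities (Fisher's
    combined probability test) with True-Skill-Statistic variable selection,
    and an evaluation suite (occurrence-probability change maps, distribution
    centers, dominance and replacement analyses, Shannon diversity, and
    ensemble-uncertainty partitioning). A synthetic-data generator provides
    climate worlds and species with known envelopes so every stage is
    exercisable and checkable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
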