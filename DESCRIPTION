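Package: tmtvar
Title: Analytical and Biological Variation of Plasma Proteins from
    Duplicate-Design TMT Proteomics
Version: 0.1.0
Authors@R:
    person("tmtvar", "developers", email = "tmtvar@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating analytical and inter-individual
    biological variation of plasma proteins from multiplexed isobaric-tag
    (10-plex TMT) experiments run in a duplicate design. Provides reporter
    ion isotope-impurity correction, global equal-sum normalization,
    pooled-control scaling and relative quantification; per-protein
    decomposition of total variation into analytical and biological
    coefficients of variation from duplicate preparations; percentile-based
    power analysis and sample-size grids with bootstrap confidence
    intervals; comparison against reference biological-variation values;
    and a synthetic-data generator with known ground truth so every stage
    can be verified without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
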