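Package: scaffoldpick
Title: Rational Minimization of Natural-Product Screening Libraries by
    Scaffold Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Greedy selection of natural-product extracts that maximizes
    MS/MS scaffold diversity, starting from a classical molecular-networking
    node table. Includes random-selection baselines with coverage curves and
    hit-rate quartiles, MZmine-style quantitative feature-table preprocessing
    (repetitive-m/z removal, fivefold blank removal, TIC normalization,
    minimum-presence filtering), Spearman/Pearson feature-bioactivity
    correlation with Benjamini-Hochberg FDR control, retention analysis of
    bioactive candidate features in minimized libraries, a screening-cost
    break-even model, and a synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
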