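Package: punctaquant
Title: Automated Quantification of Synaptic and Extrasynaptic AMPAR Puncta
    on Spinal Motor Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for automated confocal quantification of synaptic versus
    extrasynaptic AMPA-receptor subunit puncta on ventral-horn motor neurons:
    tissue-aligned systematic sampling grids built from anatomical landmarks,
    control-derived intensity thresholding, Richardson-Lucy deconvolution,
    pixel-wise colocalization counting through z-stacks, peak-plane selection
    and a 2-micron plasma-membrane "optical fraction" band, together with
    quantitative fluorescent Western-blot normalization and linear-range
    selection, nociceptive stimulation schedules, operant spinal-learning
    behavioral metrics, and the accompanying statistical battery (ANCOVA with
    a loading-control covariate, LSD pairwise comparisons on estimated
    marginal means, Tukey HSD, t and Mann-Whitney U tests, eta squared,
    observed power). A synthetic-data module generates image stacks, Western
    datasets, and behavioral cohorts with known ground truth so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    emmeans,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
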