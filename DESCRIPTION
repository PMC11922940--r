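Package: stressdose
Title: Drought Stress Dose Metrics and Post-Drought Recovery in Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify drought stress dose and post-drought recovery in
    trees from whole-tree chamber gas exchange, point-dendrometer traces,
    needle water potential, xylem vulnerability curves and hydraulic damage
    records. Computes canopy transpiration and conductance from flow-through
    chamber records, partitions dendrometer traces into growth and tree water
    deficit under the zero-growth concept, fits Weibull vulnerability curves
    with bootstrap confidence intervals for P12 and P50, derives per-tree
    stress metrics (minimum water potential, days below P12, cumulative tree
    water deficit, cumulative water potential), and ranks the metrics by how
    well they explain recovery of transpiration and conductance. A synthetic
    experiment generator with known ground truth supports end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    minpack.lm,
    multcomp,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
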