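Package: mitomorph
Title: Quantification of Mitochondrial Network Morphology, Membrane
    Potential and Metabolic Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify mitochondrial network fragmentation from
    fluorescence micrographs using the convex-hull solidity index, to
    compare intensity distributions between matched cell lines with
    per-centile quantile-difference curves and paired tail tests, to
    correct flow-cytometry TMRM intensities for cell size and
    granularity, to quantify lipid droplet areas, to test
    electron-microscopy aberrant-mitochondria proportions, and to
    analyse isotopomer fractional-abundance tables with PCA bi-plots
    and an empirical-Bayes moderated group test. A synthetic-data
    generator with planted ground truth emulates the microscopy,
    cytometry and mass-spectrometry inputs so every stage of the
    pipeline can be exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    grid,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
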