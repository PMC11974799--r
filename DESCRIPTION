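Package: quickprot
Title: Downstream Analysis of DIA and PRM Mass-Spectrometry Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Downstream analysis and visualization toolkit for
    data-independent acquisition (DIA) and parallel reaction monitoring
    (PRM) proteomics quantification exports. Reads DIA-NN report tables
    and Skyline CSV exports, applies peptide/protein filters and
    peptide-to-protein rollup, computes replicate quality-control metrics
    (coefficient of variation, Spearman correlation, MS points across
    chromatographic peaks), peptide/protein yields and shared/unique
    protein breakdowns, hierarchical clustering and correlation matrices,
    volcano differential-abundance analysis, offline over-representation
    enrichment from GMT gene sets, and stable-isotope-dilution PRM
    absolute quantification (copies per nucleus or cell) with
    ANOVA/Tukey post-hoc statistics and compact letter displays.
    Includes synthetic fixture generators with planted ground truth and
    a command-line pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    optparse
Config/testthat/edition: 3
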