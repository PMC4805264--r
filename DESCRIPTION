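Package: netretest
Title: Test-Retest Reliability of Resting-State Network Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A pipeline for quantifying between-session reproducibility of
    resting-state fMRI network connectivity. Estimates subject-specific
    network time courses and spatial maps by two-stage dual regression
    against a set of template network maps, builds entire-network and
    per-subject suprathreshold overlap (Z > 0) region-of-interest masks,
    and summarises test-retest reliability per network and group with the
    intraclass correlation coefficient ICC(3,1) from a two-way ANOVA
    decomposition and the Dice ratio of overlapping suprathreshold voxels
    (R12), including threshold-sensitivity sweeps and between-group
    comparisons with Bonferroni adjustment. Ships a synthetic 4D BOLD
    generator with controlled between-subject and between-session variance
    components so the whole pipeline can be exercised against known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
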