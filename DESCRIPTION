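Package: astrotraj
Title: Reactivity Trajectory Analysis for Astrocyte Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for ordering astrocyte nuclei along a
    reactivity trajectory from single-nucleus RNA-seq counts and screening
    the transcriptome for trajectory-associated genes. Provides quality
    control and library-size normalization, PCA/kNN neighbor graphs with
    Leiden clustering and Wilcoxon marker annotation (including doublet
    flagging), diffusion-map pseudotime with a homeostatic root rule,
    a rank-uniformized per-gene linear regression screen with effect-size,
    variance and Bonferroni thresholds, random-intercept mixed models
    linking pseudotime to donor pathology and genotype, gene-set overlap
    and transcription-factor enrichment statistics built on exact-test
    primitives, immunofluorescence count comparisons, and a negative
    binomial synthetic-data generator with planted gene programs and
    doublets for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    lme4,
    fgsea,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
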