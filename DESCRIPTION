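Package: coremarkr
Title: Core SNP Marker Sets for Crop Variety Identification and DUS Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A genome-wide-association-guided pipeline for building core SNP
    marker panels that uniquely identify crop varieties and support
    distinctness, uniformity and stability (DUS) testing. Provides per-marker
    summary statistics (minor allele frequency, call rate, polymorphism
    information content) and threshold filtering, per-trait association
    scans with top-K pooling and positional deduplication, annotation-aware
    candidate selection, minimal nested distinguishing marker sets by greedy
    set cover with identification certificates, genotype distance matrices
    with UPGMA and neighbor-joining trees plus bootstrap support, K-medoids
    population clustering, PCA and linkage-disequilibrium decay summaries,
    and cluster-versus-trait evaluation with one-way ANOVA and Duncan's new
    multiple range test. A seeded synthetic variety-panel generator emulates
    structured panels of inbred and F1 hybrid varieties so the whole funnel
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
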