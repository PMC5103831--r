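Package: seriesbin
Title: Time-Series Differential-Coverage Genome Binning and Community
    Profiling for Soil Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs genome bins from metagenome assemblies by combining
    per-scaffold coverage series across a multi-sample time/depth design with
    tetranucleotide composition signatures, trained on a toroidal emergent
    self-organizing map (ESOM) whose U-matrix valleys delineate bins. Includes
    single-copy marker-gene completeness and contamination quality control,
    ribosomal protein S3 (rpS3) species-level greedy centroid clustering with
    percent-abundance community profiles, phylum rollups and Bray-Curtis
    principal coordinates ordination, and one-way ANOVA / Benjamini-Hochberg /
    Tukey HSD group statistics for metabolite-style grouped measurements. A
    seeded synthetic soil-community generator with a full truth table supports
    parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
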