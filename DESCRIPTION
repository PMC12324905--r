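Package: morsR
Title: Cell-Lysis Profiling of Marine Protists from Paired Cell-Free and
    Cell-Associated rRNA Metabarcoding
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a Mortality-by-Ribosomal-Sequencing (MoRS) analysis
    pipeline for marine microeukaryotes: paired cell-associated / cell-free
    18S rRNA amplicon count tables are filtered, rarefied and contrasted with
    a native TMM-normalised negative-binomial GLM likelihood-ratio test to
    derive per-ASV cell-lysis (CLI) and epipelagic-enrichment (EEI) indices;
    habitat preference is classified by Gaussian kernel-density mode analysis;
    lysis and habitat calls are cross-classified (intersections, Sankey
    contingencies, rank correlations); community structure is summarised with
    Bray-Curtis dissimilarity, Ward.D2 clustering and permutation ANOSIM; and
    extracellular rRNA decay experiments are fitted with first-order kinetics.
    A synthetic community generator with known lysis and habitat ground truth
    makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metagenomics, Microbiome, Sequencing, DifferentialExpression,
    Normalization, Clustering, Software
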