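Package: dipkit
Title: Forensic and Population-Genetic Evaluation of Biallelic
    Insertion/Deletion Marker Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating multiplex deletion/insertion polymorphism
    (DIP) panels for forensic genetics: per-locus forensic parameters
    (heterozygosity, polymorphism information content, match probability,
    powers of discrimination and exclusion, paternity index) and their
    panel-wide cumulative indices; exact Hardy-Weinberg and two-locus EM
    linkage-disequilibrium screening with Bonferroni thresholds; a
    simulation-based full-sibling likelihood-ratio power study; pairwise
    Weir-Cockerham FST, Nei DA distances, Rosenberg informativeness for
    assignment and hierarchical AMOVA; PCA, classical MDS and
    neighbour-joining trees; biogeographic-origin classification with
    exact binomial confidence intervals; and a hierarchical
    Balding-Nichols generator of population-structured genotype data.
    Genotypes are held in a SummarizedExperiment-derived container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    randomForest,
    xgboost,
    e1071,
    rpart
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Genetics, SNP, StatisticalMethod, Classification
RoxygenNote: 7.3.3
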