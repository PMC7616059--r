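Package: schichubs
Title: Multiway Chromatin Hubs, Chromosome Intermingling and Bursting
    Kinetics from Single-Cell Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects multiway chromatin hubs in single-cell Hi-C contact
    maps with a separation-preserving permutation null and empirical FDR,
    computes restraint-based 3D genome structures by hierarchical simulated
    annealing of a particle-on-a-string polymer, scores inter-chromosomal
    intermingling from structure ensembles, performs A/B compartment and
    saddle analysis of binned contact matrices, classifies regulatory
    elements from histone-mark tracks and tests enhancer-promoter contact
    enrichment against compartment-matched permutation nulls, clusters
    H3K27me3 promoter trajectories, and infers Poisson-beta transcriptional
    bursting kinetics from single-cell count data. A synthetic-data module
    generates ground-truthed genomes, conformations, contact lists, mark
    tracks and count matrices so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
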