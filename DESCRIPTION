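Package: sectorphylo
Title: Functional Sector Inference from Sequence Data under Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how phylogenetic correlations affect the inference
    of functional sectors and mutational effects from multiple sequence
    alignments. Provides a Metropolis Monte Carlo simulator for binary
    sequences under quadratic selection on an additive trait, evolved either
    at equilibrium or along phylogenetic trees (perfect binary or arbitrary
    newick); site-scoring methods (ICOD, covariance, SCA, mutual information,
    conservation) with pseudocount-corrected frequency estimation and the
    average product correction; evaluation metrics (recovery, null recovery,
    symmetrized AUC, spectral analyses, earliest-mutation-generation scores);
    and a natural-MSA pipeline (gap filtering, Jukes-Cantor phylogenetic
    cutoffs, gap imputation, multi-cutoff eigenvector aggregation, deep
    mutational scan binarisation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
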