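Package: annealr
Title: Structure-Based Comparison and Screening of Single-Strand Annealing Proteins
Version: 0.1.0
Authors@R:
    person("annealr", "developers", email = "annealr@example.org", role = c("aut", "cre"))
Description: Tools for structural phylogenomics of the Rad52/RecT/Redbeta/Erf/Sak3
    single-strand annealing protein (SSAP) superfamily: reading predicted and
    experimental structures in PDB format with per-residue confidence (pLDDT)
    stored in the B-factor column, confidence filtering, TM-score structural
    alignment with a TM-align-style iterative heuristic, Calpha-geometry
    secondary-structure assignment and motif composition statistics,
    average-linkage structural dendrograms with medoid representative
    selection, tiered TM-score screening against representatives, oligomeric
    ring feasibility checks by chain-wise superposition and steric clash
    counting, and a deterministic synthetic-structure generator so the whole
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
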