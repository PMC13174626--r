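Package: funbench
Title: Time-Delayed Benchmarks and Ontology-Aware Evaluation for Protein
    Function Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds time-delayed No-Knowledge / Limited-Knowledge /
    Partial-Knowledge benchmark sets for protein function prediction from
    two Gene Ontology annotation snapshots, and scores ontology-structured
    predictions with macro- and micro-averaged Fmax, information-accretion
    weighted Smin, coverage, and bootstrap confidence intervals. Includes
    an OBO ontology reader with ancestral propagation, GAF-style annotation
    filtering with the experimental evidence-code rules used by the CAFA
    community challenges, Naive and sequence-similarity transfer baselines,
    and a synthetic-fixture generator so the whole pipeline is testable
    without external downloads.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
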