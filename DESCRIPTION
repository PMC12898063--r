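Package: rbpkmer
Title: Sequence-Based Modelling of RNA-Protein Interactions from CLIP Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling RNA-binding protein (RBP) interaction sites
    from CLIP-style peak data using k-mer sequence features. Windows of RNA
    are represented as concatenated 3-/5-mer frequency vectors and reduced
    with universal-family feature hashing expressed as a column-stochastic
    linear operator. Per-protein logistic classifiers (with a linear SVM
    baseline) are trained on peak-derived positives and genome-sampled
    negatives under leakage-safe chromosome and protein splits, and applied
    as sliding-window binding-probability tracks along arbitrary RNAs.
    Trained models are interpreted against position weight matrices and
    RNAcompete-style 7-mer affinity profiles, and in vivo versus in vitro
    interaction spaces are compared through SVD of joint protein-RNA
    matrices. A synthetic-data module simulates genomes with planted motifs,
    expression-biased peak emission, protein embeddings and 7-mer z-score
    tables so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    IRanges,
    jsonlite,
    Matrix,
    nnet,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
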