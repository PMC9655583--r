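Package: rnadsn
Title: Domain-Separation Transfer Learning for mRNA 5-Methyluridine Site
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts 5-methyluridine (m5U) modification sites on mRNA from
    41-nt sequence windows by transfer learning from the abundant tRNA m5U
    sites. Implements a domain-separation network with a shared encoder, two
    domain-private encoders, per-domain decoders and classifiers trained
    against a composite objective (reconstruction, orthogonality, maximum mean
    discrepancy, and classification losses), together with the surrounding
    pipeline: FASTA/site-table ingestion, window extraction and one-hot
    encoding, transcript-level negative sampling, a 6 x 6 = 36-fold
    cross-validation design, an evaluation metric suite, classical source-only
    baselines, and Integrated-Gradients attribution with seqlet-based motif
    aggregation. Ships a synthetic paired-domain generator with planted motifs
    so the transfer-learning behaviour is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
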