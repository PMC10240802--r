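Package: ldafgan
Title: Association-Filtering Generative Adversarial Networks for
    lncRNA-Disease Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts lncRNA-disease associations from a sparse 0/1
    association matrix with a generative adversarial model (LDAF-GAN).
    The generator emits per-lncRNA disease-score rows which are passed
    through an association-filtering operator (FUA) before reaching the
    discriminator, so training only sees entries with defined status;
    per-row negative sampling with a squared-error regulariser keeps
    generated positives near 1 and sampled negatives near 0.  An optional
    sequence-conditioned variant embeds each lncRNA's nucleotide sequence
    via overlapping k-mer tokens and a spectral document embedding,
    enabling cold-start prediction for lncRNAs with no known
    associations.  Includes entry-level k-fold cross-validation with
    ROC/PR metrics, ranked-prediction protocols, a synthetic-data
    generator with planted recoverable structure, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
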