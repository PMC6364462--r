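Package: phenorank
Title: Phenotype-Driven Prioritization of Causative Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the variants in a patient's VCF by how likely each is to be
    causative for the patient's phenotypes. Combines per-variant pathogenicity
    scores (CADD/DANN/GWAVA-style lookup tables) with ontology-based semantic
    similarity between the patient's phenotype profile and gene phenotype
    profiles, encodes variants as fixed-order feature vectors with mean
    imputation and missing-value flags, and scores them with a small
    feed-forward neural network trained on balanced sets of
    (variant, disease, zygosity) instances built from pathogenic/benign
    variant knowledge with two negative-sampling strategies. Includes a
    deterministic synthetic-data generator, spike-in synthetic-patient
    benchmarking (top-k recall, ROC AUC, AUPR) and disease-stratified nested
    cross-validation.
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
    jsonlite,
    pROC,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
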