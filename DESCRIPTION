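Package: nactresp
Title: Predicting Neoadjuvant Chemotherapy Response from Paired DCE-MRI
    with a Dual-Branch Spatio-Temporal Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting clinical response to neoadjuvant
    chemotherapy (RECIST responders versus non-responders) from paired
    pre-treatment and post-first-cycle dynamic contrast-enhanced breast
    MRI. Implements a dual-branch spatio-temporal vision transformer with
    tokens-to-token soft-split embedding, multi-scale local-global
    attention fusion, image-specific dynamic position embeddings combined
    with sinusoidal temporal embeddings, and an adaptive feature-fusion
    classification head, together with the cohort preprocessing pipeline
    (eligibility filtering, labelling, patient-level splitting, rigid
    slice alignment, breast masking, augmentation), a training and
    cross-validation harness with AUC/accuracy/sensitivity/specificity
    reporting, DeLong, McNemar and paired t model comparisons, and a
    synthetic paired-DCE-MRI phantom generator so the whole system is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    EBImage,
    RNifti
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
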