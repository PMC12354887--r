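Package: cohortvec
Title: Longitudinal Patient Embeddings from Coded EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns fixed-length numeric representations of patients from
    longitudinal coded electronic-health-record events (ICD-9/ICD-10
    diagnoses, CPT-4 procedures with age stamps). A variational autoencoder
    compresses each code's age-frequency profile into a 50-dimensional
    vocabulary embedding; a transformer without positional encodings is
    pre-trained to predict next-year code sentences under 20% masking; a
    siamese feed-forward tower fine-tunes pooled year vectors on
    same-patient and next-event pair tasks. Downstream tools cover
    phenome-wide disease-onset prediction and bulk phenotyping with
    logistic classifiers, Gaussian-mixture comorbidity subtyping with BIC,
    covariate-adjusted comorbidity enrichment, Kaplan-Meier survival
    contrasts, and post-onset progression analysis. A synthetic-cohort
    generator with planted subtypes, comorbidity signatures and mortality
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    mclust,
    survival,
    pROC,
    car,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
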