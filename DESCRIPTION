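Package: cohortgnn
Title: Population-Graph Classification of Cognitive Decline from
    Neuropsychological Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-similarity population graphs from tabular
    neuropsychological and demographic features (MMSE, MoCA, FAB, HDRS, age,
    education, sex, comorbidity, treatment, rehabilitation) and classifies
    subjects into control, amnesic mild cognitive impairment (MCI), and mild
    Alzheimer's disease (AD) groups with three neural models: a multilayer
    perceptron baseline, a graph convolutional network, and a graph attention
    network. Includes a configurable synthetic cohort simulator matching the
    published group structure of a memory-clinic sample, RBF-kernel similarity
    graph construction with percentile edge sparsification, class- and
    sex-stratified data splits, full-batch Adam training with grid search, and
    weighted precision/recall evaluation with confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
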