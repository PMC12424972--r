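Package: neurocpm
Title: Connectome Embedding and Predictive Modeling of Behavioral Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A connectome-based predictive modeling toolkit for resting-state
    fMRI parcel timeseries. Implements motion censoring, nuisance regression
    and zero-phase Butterworth bandpass filtering of parcellated timeseries;
    Pearson functional-connectivity matrices; per-subject node embeddings of
    the connectivity graph via biased random walks and skip-gram with negative
    sampling, aligned across subjects with orthogonal Procrustes; composite
    phenotype construction with winsorization and one-hot demographic
    encoding; robust scaling, top-k univariate feature selection and nested
    cross-validated prediction with partial least squares, ridge and gradient
    boosted trees over discovery/confirmation cohort arms; network-level
    feature-importance aggregation; and a synthetic-cohort generator with
    planted brain-phenotype effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    xgboost,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    vegan,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
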