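Package: tsann
Title: Time-Sensitive Attentive Neural Networks for Clinical Risk
    Prediction from Visit Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts asthma exacerbation risk from longitudinal
    electronic-health-record visit sequences using a hierarchical
    attention network with elapsed-time embeddings (TSANN).  Includes
    retrospective case-control cohort construction from dated
    diagnosis/medication events (index date, exacerbation date,
    365-day labeling, prediction-date selection), integer encoding of
    visit sequences with day-resolution time gaps, the TSANN forward
    and backward passes together with ablations and baselines
    (logistic regression, MLP, LSTM, attentive LSTM, single- and
    two-level attention variants), stratified cross-validated training
    with grid search and rank-based AUC evaluation, attention-weight
    interpretation at the patient and cohort level, and a synthetic
    EHR generator with planted time-localized risk factors for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
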