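Package: msnote
Title: Hierarchical Multi-Note Classification of Clinical Social Work Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts patient-level treatment administration (targeted cancer
    therapy, yes/no) from free-text clinical social work notes, and attributes
    the prediction to social-determinants-of-health (SDOH) topics. Implements
    the full pipeline: drug-name masking to prevent label leakage,
    medication-based patient labeling, patient-level train/validation/test
    splitting, a trainable bag-of-embeddings note classifier with early
    stopping, a two-phase hierarchical MS-n model that concatenates frozen
    note representations and fits a multilayer-perceptron head, macro-averaged
    evaluation with dummy baselines and median-over-runs reporting, and
    keyword-ablation feature importance with frequency normalization. A
    synthetic-corpus generator with planted, class-dependent topic signal
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
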