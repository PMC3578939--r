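Package: bcicalib
Title: Collaborative Calibration of Subject-Specific Physiological Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for shortening the calibration session of subject-specific
    classifiers of neural and physiological feature data (e.g. passive
    brain-computer interfaces that recognise task difficulty from EEG, EDA,
    respiration and ECG features). Implements transfer learning that selects
    classifier hyperparameters with ties broken on auxiliary data from the
    most similar other subject, inverse-accuracy active class selection with a
    no-consecutive-repeat constraint for requesting new online training
    samples, and their combination, together with a 29-feature extraction
    pipeline for raw multichannel recordings, a synthetic multi-subject pool
    generator, and an evaluation harness producing learning curves,
    samples-saved percentages and Holm-corrected paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    optparse,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
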