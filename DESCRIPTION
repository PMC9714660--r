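Package: rjafinder
Title: Automated Detection of Responding-to-Joint-Attention Gaze Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and counts responding-to-joint-attention (RJA)
    gaze-following events in eye-tracking recordings of participants
    watching actor-cueing video clips. Implements an I-VT
    velocity-threshold fixation filter with gap filling and binocular
    averaging, area-of-interest geometry (face / target / non-target
    centers, radii and the face-to-target benchmark vector), a
    four-criterion face-to-target fixation-sequence detector, valid
    sampling-rate quality control with a 60 percent inclusion rule,
    evaluation statistics (percent agreement, Cohen's kappa,
    Mann-Whitney U with effect-size r, Fisher's exact test, Spearman
    correlations with Benjamini-Hochberg correction, linear age trends),
    and a two-feature logistic classifier of ASD versus typically
    developing children with cross-validation, ROC/AUC and regression
    diagnostics. A seeded synthetic gaze generator produces 300 Hz
    binocular sessions with ground-truth events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    generics,
    pracma,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    purrr,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
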