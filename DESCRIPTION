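Package: pescale
Title: Prediction-Error Scaling Analysis for Cued Statistical-Learning fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for fMRI studies asking which
    level of visual surprise drives prediction-error responses after
    statistical learning. Generates probabilistic cue-image experimental
    designs (7:1 transitional probabilities), layered stimulus feature
    hierarchies and representational dissimilarity matrices (RDMs), and
    synthetic 4D BOLD data with planted ground truth; implements trial-wise
    surprise scoring, parametric-modulation GLMs with a double-gamma HRF,
    least-squares-separate single-trial estimation, searchlight
    representational similarity analysis (Kendall tau-a), surprise-scaling
    regression with best-layer maps, linear-SVM decoding, and behavioural
    statistics (Greenhouse-Geisser repeated-measures ANOVA, Holm post-hocs,
    Cousineau-Morey within-subject intervals, JZS Bayes factors).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    yaml,
    RNifti,
    e1071,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
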