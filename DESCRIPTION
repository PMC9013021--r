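Package: riskpattern
Title: Interpretable k-of-m Pattern Discovery for Imbalanced Clinical Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers interpretable risk patterns (sets of variable-value
    conditions with an optimized k-of-m matching threshold) from mixed-type
    clinical cohort tables with rare binary outcomes. Numeric predictors are
    binarized at the cutoff of maximal information gain; a greedy heuristic
    grows the condition set while exhaustively re-optimizing the matching
    threshold. Three knowledge-incorporation modes are supported: purely
    data-driven discovery, clinician edits with data-driven threshold
    re-optimization, and data-free clinician refinement. Evaluation under a
    chronological train/test split uses an imbalance-aware metric panel
    (sensitivity, specificity, precision, F-score, G-mean, tie-grouped
    trapezoidal ROC/AUC, optimal ROC points) plus train-versus-test cohort
    comparison statistics. Includes a synthetic cohort generator with planted
    patterns and concept drift, outcome labeling from creatinine pairs, 1:1
    resampling, and a command-line workflow.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
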