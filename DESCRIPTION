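Package: milrel
Title: Reliability Evaluation of Multiple Instance Learning for Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the reliability of multiple instance learning (MIL)
    models for whole-slide image classification: whether the patch scores a
    trained aggregator emits (attention weights, instance probabilities, or
    max-pool selections) actually concentrate on annotated regions of
    interest. Provides the standard MIL aggregator family (mean/max pooling,
    instance-level pooling, gated-attention ABMIL and its clustering,
    multi-head, multi-branch and two-tier pseudo-bag derivatives, plus exact
    additive reformulations), per-patch score extraction, three reliability
    metrics (mutual information, Spearman correlation, area under the
    precision-recall curve) computed against polygon-annotation-derived patch
    labels, exact parameter and FLOP accounting, a multi-seed training and
    benchmarking harness on synthetic feature bags with planted regions of
    interest, and cross-dataset aggregation and metric-exclusion ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
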