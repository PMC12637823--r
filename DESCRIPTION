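Package: oligostate
Title: Stoichiometry Prediction for Protein Complexes from Subunit
    Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the stoichiometry (per-subunit copy numbers) of
    homo- and hetero-oligomeric protein complexes from fixed-length
    per-subunit embedding vectors, such as mean-pooled protein language
    model representations.  The core predictor is a masked multi-head
    additive graph attention network over the unique subunits of a
    complex, with a local per-subunit copy-number head and a conditional
    mixture-of-experts head for the global composition; candidate
    stoichiometries are ranked by beam search over the product of
    chain-level distributions and re-scored by a weighted combination of
    local and global probabilities.  Also provides a template-hit
    weighted-voting predictor, a training-set frequency baseline with a
    shuffle-and-average evaluation protocol, top-N / micro-F1 / macro-F1
    evaluation with rare-class aggregation, dataset-curation utilities
    (composition deduplication, time splits, redundancy filtering with
    optimal chain mapping), and a synthetic-data generator with a
    planted copy-number signal for desk-scale training and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
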