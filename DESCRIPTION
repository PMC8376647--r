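Package: ihctriage
Title: Triage of Prostate Biopsy Slides for Advance Immunohistochemistry Ordering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline that decides, from an H&E whole-slide
    image alone, whether immunohistochemistry (IHC) should be requested in
    advance for a prostate needle biopsy. Tissue is segmented and tiled, an
    ensemble of small neural tile classifiers recognises ambiguous epithelial
    morphology and quantifies its own uncertainty, per-slide distribution
    statistics of tile embeddings feed a gradient-boosted decision model, and
    a workflow-economics module converts classifier operating points into
    turnaround-time savings, reporting-time savings, and the cost of
    unnecessary IHC orders. A synthetic needle-biopsy image generator makes
    every stage trainable and testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
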