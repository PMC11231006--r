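Package: surgvqa
Title: Scene-Graph Driven Generation and Auditing of Surgical Visual
    Question Answering Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds attributed scene graphs from per-frame surgical object
    detections and <instrument, verb, target> action triplets, instantiates
    template-based questions through executable functional programs, and
    curates the resulting question-answer pairs with phase-balanced frame
    sampling, template blocklists, degenerate-question elimination and
    answer-frequency rebalancing. Ships text-only probes (majority and
    multinomial naive Bayes) to quantify question-condition bias, a
    seed-deterministic synthetic procedure generator for laparoscopic
    cholecystectomy streams, dataset statistics reporting, and a desk-scale
    reference implementation of a scene-aware VQA network: scene encoder,
    scaled dot-product attention, a scene-embedded interaction module,
    RoIAlign pooling and a fusion classifier trained by a small built-in
    reverse-mode autodiff.
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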