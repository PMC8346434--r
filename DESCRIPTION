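Package: larvafeed
Title: High-Throughput Analysis of Leaf-Disk Feeding Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify insect herbivory from time-lapse images of
    multi-cage leaf-disk feeding plates. Detects the cage grid inside a
    user-drawn parallelogram by a line-variance heuristic, segments leaf
    pixels with arithmetic RGB, HSB or reference-colour distance filters,
    counts leaf area per cage per frame, standardizes the series into
    fraction-of-intact-disk consumption curves, classifies curves into
    behavioural types by two-fold clustering (a self-organizing tree
    algorithm followed by K-means on curve features), and compares
    treatments with multinomial logistic models, AIC selection and Wald
    contrasts. A synthetic-data module renders ground-truthed plate image
    stacks and consumption curves so the whole pipeline is testable
    without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jpeg,
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
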