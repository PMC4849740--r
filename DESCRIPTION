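Package: shapersa
Title: Representational Similarity Analysis of Shape Perception Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing model representations of object shape with
    human similarity judgments. Implements shallow image feature models
    (pixelwise, Gabor jet, histogram of oriented gradients), construction
    and comparison of representational dissimilarity matrices (RDMs),
    a matching-distance consistency statistic for naming accuracy,
    stratified bootstrap confidence intervals and paired group tests,
    noise-ceiling estimation from per-participant RDMs, and synthetic
    generators for stimulus sets, simulated observers, layer activations
    and non-accidental-property triplets so the full pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
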