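Package: matfp
Title: Visual Fingerprints of Material Appearance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing material appearance as a 16-attribute
    perceptual "visual fingerprint". Aggregates psychophysical slider ratings
    into fingerprints (participant-level z-scoring, discordant-rater
    exclusion, inter-rater agreement statistics), computes a correlation plus
    L1 fingerprint similarity metric with retrieval and typicality, extracts
    image-computable feature sets from non-specular/near-specular image pairs
    (compact image statistics, steerable-pyramid texture-synthesis statistics,
    pluggable deep embeddings), predicts fingerprints from features with
    nearest-neighbour interpolation or small multilayer perceptrons, and
    evaluates predictions with similarity-matrix and rating-level variance
    explained, retrieval overlap, rank correlation, and AIC model comparison.
    A procedural material generator with simulated raters makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
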