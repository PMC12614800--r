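Package: fearca
Title: Multi-Day Calcium Imaging Analysis of Amygdala Interneurons in Fear
    Conditioning and Extinction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for multi-day single-cell calcium
    recordings acquired during discriminative auditory fear conditioning and
    extinction. Provides the canonical data model for sessions, stimulus
    events and cross-day-registered fluorescence traces; event-aligned
    preprocessing (z-scoring, 250 ms binning, baselining, AUC); rank-sum
    responsiveness classification; response-archetype discovery by PCA and
    K-means with silhouette evaluation, cluster merging and template
    labelling; population-vector-distance geometry with cluster-removal
    ablations; linear-SVM population decoding with cross-validation,
    cross-day transfer and shuffled-label controls; pose-based immobility
    detection with immobility-aligned neural activity and a behavioural
    discrimination score; and a synthetic-data generator that plants known
    response archetypes and immobility bouts so that every stage of the
    analysis can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    e1071,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
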