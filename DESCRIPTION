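Package: delphen
Title: Two-Stage K-Means Phenotyping of Longitudinal Delirium Symptom Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hypothesis-free phenotyping of longitudinal ordinal
    symptom-severity data such as daily Delirium Rating Scale-Revised-98
    (DRS-R-98) severity assessments. Implements a two-stage K-means
    pipeline: item-by-day feature columns are first clustered into grouped
    symptom features, the score matrix is collapsed to per-group composite
    means, and participants are then clustered on the composites. The
    number of clusters at each stage is chosen by an Akaike information
    criterion over a multi-restart, reproducibly seeded Lloyd's algorithm.
    Clusters are ordered by peak total severity, labelled by the majority
    of categorical diagnoses, and characterized post hoc with
    Bonferroni-corrected one-sample t-tests and across-cluster analysis of
    variance. Includes principal-component views of both stages and a
    synthetic-cohort generator with planted feature groups and participant
    archetypes so the full pipeline can be exercised and validated without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
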