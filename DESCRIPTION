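Package: triagerec
Title: Symptom-Based Department Triage and Doctor Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid recommender toolkit for outpatient appointment
    platforms. Builds TF-IDF symptom vector spaces from tokenized chief
    complaints, score-weighted department profiles that up-weight visits
    with high post-visit ratings, department triage by mean-centered
    (adjusted) cosine similarity, trust-weighted K-means clustering of a
    department's historical patients with elbow selection of k, and
    doctor recommendation by alternating-least-squares densification of
    the neighbor patient-doctor rating matrix followed by mean-centered
    user-based collaborative filtering. Includes a reproducible synthetic
    clinic simulator, a precision/recall evaluation harness for
    before/after-clustering comparisons, and standalone numerics for a
    registration-review pipeline (multi-scale 1-D convolution,
    maximum-value wave-function eigenvalue correction, softmax head).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Matrix,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
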