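Package: dyadsync
Title: Dyadic Analysis of Personality Similarity and Inter-Subject Neural Synchrony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dyadic analyses linking personality similarity to
    inter-subject neural synchrony. Provides trait and facet scoring of Big
    Five questionnaires, dyadic similarity metrics (Euclidean, Manhattan,
    Canberra, supremum, and socio-demographic codings), region-level fMRI
    synchrony (magnitude and spatial-pattern inter-subject correlation),
    correlated-components analysis for multichannel EEG epochs, earth
    mover's distance gaze similarity, and a dyadic inference layer with
    subject-shuffling (Mantel-style) permutation tests, FDR correction,
    per-network coefficient tests, per-subject effect distributions,
    mediation analysis, and effect-size comparisons. A synthetic
    multi-subject generator with a closed-form correlation oracle and a
    tunable personality-synchrony coupling supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
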