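Package: drmtrack
Title: Distributional Semantics and Mouse-Tracking Analysis of DRM False
    Memories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the decision dynamics of false recognition
    in the Deese-Roediger-McDermott (DRM) paradigm with distributional
    semantics and mouse tracking.  Computes a frequency-weighted semantic
    similarity index (SSim) between recognition probes and studied list
    words from word embeddings in word2vec text format; extracts
    trial-level decision-dynamics measures (maximum deviation, sample
    entropy, MD-time, initiation reaction time) from raw mouse
    trajectories after 101-step time normalization and symmetric
    remapping; applies the standard trial-exclusion rules; and fits
    generalized and linear mixed models with crossed participant and item
    random intercepts, including singularity fallback, model criticism,
    contrast-based simple slopes, and simulation-based observed power.  A
    fully seeded synthetic-experiment generator with known ground-truth
    parameters supports end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
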