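Package: n400stack
Title: Surprisal, Agent Preference, and Topographic Modeling of N400
    Amplitudes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A simulation and analysis pipeline for studying whether
    language-model surprisal suffices to predict N400 amplitudes at
    sentence-final verbs, or whether a binary Agent Preference
    (reanalysis) predictor is additionally required. Provides generators
    for toy verb-final languages with configurable case alignment,
    syncretism and word order; count-based incremental language models
    with vocabulary capping and critical-word surprisal extraction; a
    permutation-based grammaticality test and hierarchical Student-t
    condition contrasts; a generator of single-trial window-mean ERP
    amplitudes over a 2D electrode layout with known topographic effects;
    additive models with tensor-product spline smooths over electrode
    coordinates and topographic random effects; and leave-one-out
    predictive stacking of candidate models, so that parameter and model
    recovery can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    ggplot2,
    jsonlite,
    lme4,
    mgcv,
    rjags,
    rlang,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
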