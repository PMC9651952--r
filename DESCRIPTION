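Package: conjrsa
Title: Single-Trial EEG Decoding and Conjunction RSA for Prioritized Action Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how multiple planned actions are held and
    selected in working memory with time-resolved EEG multivariate analysis.
    Implements a rule-selection task model (three spatial rules mapping four
    stimulus locations to responses, two concurrently planned actions with
    70/30 test priority, and an adaptive response deadline), a synthetic
    epoched-EEG generator with planted rule, stimulus, response and
    conjunction codes, Morlet wavelet band-power features, time-resolved
    12-way shrinkage-regularized linear discriminant decoding with repeated
    stratified cross-validation, single-trial representational similarity
    analysis by regression of logit classification probabilities on model
    vectors, cluster-based permutation statistics over time, and multilevel
    models linking representation strength to trial-to-trial behavior.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
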