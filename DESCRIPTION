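Package: sleepuq
Title: Uncertainty-Guided Clinician-in-the-Loop Sleep Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Probabilistic single-channel sleep staging with per-epoch
    uncertainty quantification and targeted-review simulation. Stagers (a
    kernel-density-emission hidden Markov model decoded by the
    forward-backward algorithm, and a multilayer perceptron with softmax
    outputs) emit per-epoch five-class posterior probabilities over the
    stages W, REM, N1, N2 and N3. Renyi-family entropies (Shannon,
    collision, min-entropy) and posterior variance turn each posterior row
    into an uncertainty value; epochs above a 1-bit threshold are flagged
    for review. Review policies (ground-truth substitution, a simulated
    imperfect reviewer, clinically-relevant filtering) are evaluated
    against ground truth with Cohen's Kappa, certainty-stratified
    confusion matrices, and entropy-distribution summaries. A seeded
    synthetic polysomnography simulator (Markov stage dynamics,
    stage-specific EEG band spectra, an apnea-like fragmentation knob)
    makes the whole pipeline reproducible without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
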