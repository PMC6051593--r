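Package: seqstrat
Title: Markov Sequence Design, Performance and Strategy Metrics for
    Statistical Learning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for behavioral statistical-learning experiments in which
    observers predict the next symbol of a probabilistic temporal sequence.
    Implements order-0/1/2 Markov stimulus models with context-conditional
    target probabilities, candidate-sequence generation with
    Kullback-Leibler-based selection of presentation sets, training-block and
    test-run assembly, the min-overlap performance index with analytic and
    simulated random-guess baselines, the matching-versus-maximization
    strategy-choice statistic (delta-KL) and its integral-curve-difference
    strategy index, and a synthetic-observer simulator spanning the
    probability-matching to probability-maximization continuum for
    end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
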