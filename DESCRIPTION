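Package: zetatest
Title: Parameter-Free Detection of Event-Locked Neuronal Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the ZETA-test, a binless, timescale-free statistical
    test for whether a neuron's spiking is time-locked to a series of events
    (e.g. stimulus onsets). The test compares the event-aligned cumulative
    spike-time distribution against a linear baseline and calibrates the
    maximum absolute deviation against a jitter- or ISI-shuffle-resampled
    null via a Gumbel extreme-value fit. Also provides a binless multi-scale
    instantaneous firing-rate estimator with peak/onset/trough latency
    detection, classical baseline tests (paired mean-rate t-test, optimal-bin
    PSTH ANOVA, multi-timescale ANOVA, renewal-process surrogate tests),
    point-process simulators of orientation-tuned Poisson and bursting
    neurons, and ROC/AUC benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
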