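Package: ephyscohort
Title: Synthetic Intracellular-Recording Cohorts and Response-Feature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates cohorts of intracellularly recorded leech neurons
    (T3 and P1 mechanoreceptors, Retzius cells) under pseudo-randomized
    step-current stimulation and sparse control protocols, with full ground
    truth; extracts the standard response features from membrane-potential
    traces (resting membrane potential, spike and rebound-spike counts,
    first-spike latency, inter-spike intervals, voltage-sag ratio, input
    resistance); and runs the accompanying nonparametric statistical program
    (coefficient of variation, Spearman rank correlation, Wilcoxon rank-sum
    and signed-rank tests, Bonferroni correction) to produce interdependency
    and protocol-comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
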