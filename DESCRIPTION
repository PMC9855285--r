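Package: cdafilter
Title: Contralateral Delay Activity Analysis of Visual Working Memory
    Distractor Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation-driven pipeline for lateralized event-related
    potential (ERP) analysis of visual working memory (VWM) distractor
    filtering. Generates synthetic cohorts, change-detection trial tables,
    and epoched EEG with known contralateral delay activity (CDA) ground
    truth; reads and writes BrainVision core format; preprocesses epochs
    (bad-channel interpolation, average reference, zero-phase low-pass
    filtering, baseline correction); rejects trials by HEOG and amplitude
    thresholds; computes contralateral/ipsilateral difference waves,
    window-mean component amplitudes and CDA difference scores; derives
    Cowan's K and d-prime from behavior; and runs the inferential layer
    (mixed repeated-measures ANOVA/ANCOVA with partial eta squared, planned
    t tests with Cohen's d, JZS default-prior Bayes factors, Pearson
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
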