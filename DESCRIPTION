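Package: acex
Title: Current-Clamp Excitability Features and Pain-Resilience Composites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline linking depression-like behaviour
    in rodent neuropathic-pain cohorts to anterior cingulate cortex (ACC)
    neuronal excitability. Extracts excitability features from current-clamp
    step recordings (f-I curve, spline-based rheobase, input resistance,
    resting potential, membrane time constant, action-potential waveform
    measures), screens von Frey behavioural data with a six-measure t-test
    inclusion rule, builds pooled signed z-score composites for behavioural
    resilience and neuronal excitability, and correlates the two at the animal
    level. A leaky integrate-and-fire cohort simulator with analytic ground
    truth generates complete synthetic cohorts (recordings plus behavioural
    tables) so the whole chain is testable without animal data. Includes the
    group-level statistical battery: pooled-variance t-tests, two-way ANOVA
    with Type-II sums of squares, two-way repeated-measures ANOVA, and Tukey,
    Holm-Sidak and Benjamini-Krieger-Yekutieli post-hoc corrections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    car,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
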