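Package: swimresp
Title: Intermittent-Flow Respirometry Analysis for Fish Metabolic Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing intermittent-flow respirometry oxygen traces
    and estimating fish metabolic phenotypes under three experimental
    protocols: incremental swim trials in a swim tunnel, exhaustive chase
    followed by resting respirometry, and circular-chamber exercise. Computes
    per-cycle mass-specific oxygen uptake (MO2) from oxygen-decline slopes
    with background-respiration correction, estimates maximal metabolic rate
    (MMR), standard metabolic rate (SMR), aerobic scope and critical swimming
    speed (Ucrit, Brett interpolation), applies solid-blocking speed
    corrections, and compares methods across species with repeated-measures
    linear mixed models, pairwise contrasts and compact letter displays. A
    protocol-faithful trace simulator with known ground-truth physiology
    supports end-to-end validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    emmeans,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
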