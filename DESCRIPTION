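Package: ssvepShift
Title: Electrode-Shift Robustness Analysis for SSVEP Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how robust steady-state visual evoked
    potential (SSVEP) frequency decoding is to electrode displacement on a
    dense occipital grid. Implements five training-free SSVEP classifiers
    (canonical correlation analysis and its delay-embedded extension, a
    filter-bank CCA, and the multivariate synchronization index with its
    delay-embedded extension), exhaustive enumeration of shifted channel
    combinations on a 3 x 7 electrode grid, the average classification
    accuracy (ACA) and robustness-to-electrode-shift (RES = 1 - CV)
    summary measures, repeated-measures ANOVA and Bonferroni-corrected
    post-hoc comparisons, and a seeded synthetic SSVEP generator so the
    whole pipeline is testable without recorded EEG.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
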