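Package: voclass
Title: Electronic-Nose and GC-MS Volatilome Analysis for Food Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating food samples by their volatile organic
    compound (VOC) fingerprints. Simulates six-sensor metal-oxide (MOX)
    electronic-nose resistance cycles with a stabilization-analysis-recovery
    schedule, normalizes and segments the traces, extracts an eleven-descriptor
    feature set per sensor, classifies diet-by-cooking-state classes with a
    from-scratch multi-class linear discriminant analysis, and evaluates the
    classifier with confusion matrices and one-vs-rest ROC curves with micro
    and macro AUC averaging. A companion GC-MS toolkit filters integrated peak
    tables, computes relative abundances (percent GC area), aggregates
    replicates into compound and chemical-class profiles, and compares raw
    versus cooked states.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
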