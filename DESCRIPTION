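Package: copingHRV
Title: Stress-Coping Styles from Resting Heart-Rate Variability in a Capital Breeder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of stress-coping styles in lactating grey
    seals from inter-beat-interval (IBI) heart-rate telemetry. Cleans raw IBI
    traces (extra/missed-beat correction, flat and stair artefact detection),
    segments them into 300-second windows, joins behavioural ethogram states,
    and derives resting heart-rate variability as the median RMSSD of retained
    resting windows. Estimates across-year repeatability of resting HRV via
    mixed-model variance components with parametric bootstrap, computes
    maternal reproductive-performance metrics (post-partum mass, daily mass
    loss and pup mass gain rates, mass transfer efficiency) and their annual
    deviance moduli, and fits Gaussian mixed models with all-subsets AICc
    selection and nested-model confidence-set pruning. Includes a synthetic
    colony and telemetry generator with known ground truth so every stage has
    parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
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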