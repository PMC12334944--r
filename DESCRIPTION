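Package: prri
Title: Personalized Reference Intervals from Biological Variation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes personalized reference intervals (prRIs), reference
    change values (RCVs) and the index of individuality from biological
    variation parameters (within-subject CV_I, between-subject CV_G,
    analytical CV_A) and a patient's steady-state result history, flags
    longitudinal laboratory results against population reference interval,
    prRI and RCV criteria, and simulates longitudinal complete-blood-count
    panels with steady-state multiplicative noise and pathological
    excursion windows for method validation. Ships a worked hematology
    case with ten measurands and a command-line pipeline (compute, flag,
    simulate, case-demo).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
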