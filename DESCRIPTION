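Package: edscreen
Title: Rule-Based Screening of Broad Eating-Disorder Categories from SCOFF and BMI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a clinical decision rule that combines a positive SCOFF
    screen (at least two of five positive answers) with the WHO body-mass-index
    class to allocate patients to one of four broad eating-disorder categories
    (restrictive, bulimic, hyperphagic, other). Ships a constrained
    reconstruction of the published 104-cell rule table together with loaders
    and validators for user-supplied tables, the full diagnostic-validation
    machinery (one-vs-rest sensitivity and specificity with
    continuity-corrected Wald confidence intervals, Youden index, Cohen's
    kappa), a synthetic screen-positive cohort generator for offline testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    e1071,
    withr
Config/testthat/edition: 3
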