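Package: thromboflap
Title: Decision-Analytic Model of Thrombophilia Screening Before Free Flap
    Surgery
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a screen-and-treat decision model for thrombotic
    complications of free tissue transfer. From a flap registry and matched
    billing pairs it derives the institutional thrombotic complication rate
    and the incremental direct cost of a complication; from a panel of
    thrombophilia conditions (prevalence, relative risk of first venous
    thromboembolism used as a risk proxy, test sensitivity, assay cost) it
    solves the baseline per-case thrombosis risk under a per-condition risk
    cap, predicts condition-attributable complications, and evaluates
    screening and universal-prophylaxis scenarios on a fixed cohort,
    including break-even complication costs and incremental
    cost-effectiveness ratios. A patient-level Monte-Carlo microsimulation
    and synthetic-data generators support verification of the deterministic
    expectations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
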