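Package: apixpbpk
Title: Whole-Body Physiologically Based Pharmacokinetics of Apixaban in
    Special Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-body, perfusion-limited physiologically based
    pharmacokinetic (PBPK) model of the oral anticoagulant apixaban, with
    pathophysiological scaling to renal impairment (creatinine-clearance
    based), hepatic impairment (Child-Pugh classes) and elderly physiology.
    Includes a reference-human physiology with virtual-population sampling,
    tissue to plasma partition-coefficient methods, a stiff ODE engine with
    oral absorption and event-based dosing, non-compartmental analysis
    (Cmax, AUC, terminal slope), average-fold-error model evaluation, and
    exposure-matched dose-normalization tables for special populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
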