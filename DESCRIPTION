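Package: dcrisk
Title: Dietary Comparator Ratio Screening for Acute Organophosphate
    Neurotoxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for next-generation risk assessment of acute
    organophosphate (OP) exposure based on acetylcholinesterase (AChE)
    inhibition. Fits four-parameter log-logistic concentration-response
    curves to in vitro erythrocyte AChE inhibition data, derives IC50
    values and benchmark concentrations (BMC) with parametric-bootstrap
    lower confidence limits (BMCL), and combines them with predicted
    maximum blood oxon concentrations to compute Exposure Activity Ratios
    (EAR) and the Dietary Comparator Ratio (DCR) for human exposure
    scenarios. Scenarios with DCR at or below a cutoff (default 1) are
    classified as raising no safety concern; predictions can be evaluated
    against reported human outcomes (false positive/negative analysis).
    Includes a bundled reference table of published exposure scenarios
    for six model OP pesticides and a synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
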