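Package: dietGxE
Title: Gene-Diet Interaction Analysis for Matched Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing interactions between genetic risk and
    dietary pattern adherence in nested case-control studies of obesity.
    Implements energy-density adjustment and the eight-component
    Mediterranean diet score with sex-specific median cutoffs, risk-allele
    dosage coding, allele and genotype frequency tables, Hardy-Weinberg
    equilibrium testing, weighted genetic risk scores, age- and sex-matched
    pair assembly with an auditable exclusion cascade, conditional logistic
    regression for 1:1 matched pairs fitted by Newton-Raphson on within-pair
    differences, unconditional logistic regression, likelihood-ratio
    interaction tests and quartile-median trend tests, plus a synthetic
    cohort generator with configurable gene-environment interaction effects
    for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
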