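Package: protswap
Title: Protein and Amino Acid Adequacy Under Plant-for-Animal Protein
    Substitution
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates usual protein and indispensable amino acid intakes
    from multi-day dietary records, screens energy misreporters with Henry
    basal metabolic rate equations and Goldberg/Black cut-offs, computes
    the prevalence of nutrient inadequacy by the probability approach with
    Wald confidence intervals, and simulates the graded substitution of
    animal protein by plant protein under protein- or energy-conserving
    replacement models, including mixes of legumes, nuts and seeds. A
    synthetic dietary-survey generator reproduces the statistical structure
    of a national 7-day food-record survey so every stage is testable
    without access to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
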