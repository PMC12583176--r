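Package: healthscm
Title: Synthetic Control Evaluation of Healthcare Resource Misallocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quasi-experimental evaluation of regional healthcare
    policy with the synthetic control method (SCM). Builds a city-level
    medical-resource misallocation index (absolute relative deviation of
    normalized hospital, bed and physician counts from the yearly national
    average), fits a synthetic control by nested optimization of predictor
    importance (V) and donor (W) weights on the probability simplex, and
    provides in-space and in-time placebo inference, donor-exclusion and
    sample-truncation robustness scenarios, mechanism re-estimation on
    mediator outcomes, and a seeded factor-model panel generator with known
    ground truth for validation. Motivated by evaluations of the 2012
    Sanming healthcare reform.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
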