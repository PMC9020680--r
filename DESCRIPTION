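Package: surgcomp
Title: Retrospective Surgical Complication Rates and Randomization Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for retrospective analysis of post-operative
    complications from linked surgical, prescription, and observation
    records. Implements rule-based flagging of potential complications
    (treatment prescriptions in a post-operative window, extended
    observation), keyword and override based adjudication, per-stratum
    complication rates, and a one-sided Monte-Carlo randomization test on
    the difference in complication proportions with an exact
    hypergeometric oracle. Includes a synthetic electronic-health-record
    cohort generator with known ground truth, and bundled summary tables
    from a retrospective macaque biopsy cohort for reproduction of its
    reported comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0), withr, jsonlite, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
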