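Package: factorialBF
Title: Half-Normal Bayes Factors and Evidence Updating for Factorial Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing multi-component factorial trials with Bayes
    factors under a directional half-normal prior on the effect size.
    Implements per-component main effects, enhanced/enhanced versus
    minimal/minimal two-way interaction contrasts and multi-component
    synergy contrasts on change scores or last-observation-carried-forward
    outcome levels, multi-scale prior robustness scans, evidential
    categorisation of Bayes factors, sequential "top-up" updating of a
    trial dataset with extended recruitment, planning power calculations,
    and a synthetic 2^5 factorial trial generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
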