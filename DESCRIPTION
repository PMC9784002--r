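Package: rsreval
Title: Rank Sum Ratio Evaluation of Regional Health Services
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comprehensive evaluation of regional health services with the
    non-integer Rank Sum Ratio (RSR) method: orientation-aware non-integer
    rank transformation of indicator panels, per-dimension RSR scoring,
    probit-based distribution fitting with three-level grading at probit
    cut-offs, grading validation by one-way ANOVA with Student-Newman-Keuls
    pairwise contrasts, and classification of regions into the WHO
    needs/utilization/resources comprehensive-evaluation types and five
    policy categories. Ships the provincial maternal-services evaluation
    panels for China 2009 and 2019 as plain-text fixtures, a synthetic
    indicator generator, and report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
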