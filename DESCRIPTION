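Package: shct
Title: Cooper-Test Aerobic Profiling and Super High-Intensity Continuous
    Training Programming
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for field-based aerobic training design and evaluation in
    team sport. Estimates an athlete's aerobic profile (relative and absolute
    maximal oxygen uptake, maximal aerobic speed, running economy) from the
    Cooper 12-minute run test, programs individualized four-week Super
    High-Intensity Continuous Training (SHCT) cycles with per-session oxygen
    and kilocalorie accounting, and evaluates longitudinal training effects
    with one-way within-subjects ANOVA, partial eta squared, Bonferroni
    pairwise tests, test-retest reliability (Cronbach's alpha, intraclass
    correlation) and noncentral-F power analysis. Includes a seeded synthetic
    cohort generator with the repeated-measures correlation structure the
    analyses assume, so the whole pipeline is testable without athlete data.
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
    withr,
    optparse
Config/testthat/edition: 3
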