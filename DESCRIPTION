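Package: vmnav
Title: Simulation and Analysis of Virtual Morris Water Navigation Task Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying spatial-navigation impairment in amnestic mild
    cognitive impairment (aMCI) with a virtual Morris water navigation task.
    Provides an agent-based trajectory simulator calibrated to published
    cohort summaries, extraction of the six standard navigation metrics from
    raw XY paths (path length, latency, path distance ratio, quadrant
    crossings, time in target quadrant, target crossings), nonparametric and
    mixed-effects group comparisons, Kaplan-Meier analysis of censored
    latencies, a PCA-based Route Efficiency composite, and nested
    cross-validated ROC evaluation of group discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
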