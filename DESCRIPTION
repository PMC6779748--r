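Package: relapsewatch
Title: Anomaly Detection of Psychotic Relapse from Social-Media Timelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for digital phenotyping of psychotic relapse from
    timestamped social-media archives. Segments a participant's timeline
    around hospitalization dates into periods of relapse (the month before
    an admission) and periods of relative health, extracts LIWC-style
    psycholinguistic category proportions, structural language measures
    (readability, repeatability, word length), unigram usage, and diurnal
    activity rates, screens features with paired exact Wilcoxon signed-rank
    tests, filters features by coefficient of variation, and detects relapse
    periods as anomalies with single and bagged-ensemble one-class support
    vector machines trained on periods of health. Includes a synthetic
    cohort generator with a machine-readable truth log so the whole pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
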