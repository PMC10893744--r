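Package: pancwf
Title: Pancreatic Cancer Demand, Stage-Shift and Workforce Scenario Modelling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic scenario model for pancreatic cancer service planning.
    Projects annual new cases from a registry incidence series (log-linear trend),
    decomposes them by diagnostic stage and Modified Monash remoteness band,
    simulates earlier-diagnosis stage-shift scenarios that conserve annual
    incidence, converts stage distributions into expected 5-year survivor counts
    via stage-specific relative survival, and compares case demand against
    projected specialist headcounts to flag geographic workforce gaps. Bundles
    the published Victorian 2023-2027 inputs as a fixture and includes a seeded
    synthetic registry-data generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
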