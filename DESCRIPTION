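Package: persistkit
Title: Persistence and Adherence Analysis for Prescription Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for new-user persistence and adherence studies on
    health-insurance claims data, modelled on analyses of oral antidiabetic
    therapy (SGLT2 inhibitor monotherapy) in Japanese claims databases.
    Provides a validated claims-bundle container with the year-month
    (day-15) date convention, a synthetic claims generator with planted
    ground truth, new-user cohort construction with an auditable exclusion
    cascade, gap-based discontinuation and proportion-of-days-covered (PDC)
    computation, Kaplan-Meier persistence estimation, person-year incidence,
    crude and adjusted logistic odds ratios with multicollinearity
    screening, and report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite
Config/testthat/edition: 3
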