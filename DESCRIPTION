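Package: rxpersist
Title: Medication Adherence and Persistence from Pharmacy Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds new-user cohorts from pharmacy dispensing claims and
    measures adherence and persistence to chronic oral therapy, with oral
    5-aminosalicylate (mesalamine) treatment of ulcerative colitis as the
    motivating use case. Provides the medication possession ratio (MPR) with
    80% and 50% adherence thresholds and a proportion-of-days-covered
    sensitivity variant, grace-period treatment episode construction that
    classifies discontinuation as gap, switch, or censored, Kaplan-Meier
    time-to-discontinuation with log-rank comparison, a medication-based
    chronic disease score and other claims-derived covariates, stepwise
    backward logistic regression of adherence and persistence determinants,
    and a seeded synthetic claims generator so the whole pipeline is testable
    without access to an administrative database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
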