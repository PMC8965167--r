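Package: alehosp
Title: Active Living Environments and Hospitalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analyses of active living environments
    (ALEs) and hospital burden. Derives a five-class ALE typology from
    built-environment layers (street-intersection density, points of
    interest, dwelling density within 1000 m Euclidean buffers) using
    k-medians clustering; constructs inpatient episodes from hospital
    discharge records under Welsh person-spell and Canadian
    episode-of-care rules with ICD-10 cause grouping; computes crude
    utilization statistics; and fits adjusted logistic models with
    sandwich robust variance, a log follow-up offset, and delta-method
    marginal predicted probabilities by ALE class. Includes a synthetic
    world generator (geography, cohort, hospital records) emulating the
    structure of linked survey/discharge microdata so the full pipeline
    is testable without access to confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
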