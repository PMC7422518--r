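Package: dialcohort
Title: Identify Incident Chronic Dialysis Patients from Administrative Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based case-definition algorithms that identify incident
    (newly starting) chronic dialysis patients from two routinely collected
    administrative sources: hospital discharge records (HDR) and ambulatory
    specialty visit (ASV) records. Index events are found through ICD-9-CM
    dialysis diagnosis, procedure and outpatient service codes; candidate
    patients are then filtered by residence, a 365-day prevalence lookback,
    a chronicity threshold on the span of observed dialysis (30 days, or 90
    days when dialysis followed acute kidney injury), and in-hospital death
    at the index admission. The package also provides an ICD-9-CM to
    ICD-10-CM crosswalk for the code sets involved, validation metrics
    (sensitivity, positive predictive value, percentage agreement) against a
    gold-standard dialysis registry, and a seeded synthetic-data generator
    that emulates the HDR/ASV/registry tables for every patient archetype the
    algorithms must handle, so the whole pipeline can be exercised and tested
    without access to real health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
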