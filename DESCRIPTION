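Package: amcsurv
Title: Automated Surveillance of Antimicrobial Consumption in Intensive Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes antimicrobial-consumption (AMC) surveillance metrics for
    intensive care units from timestamped medication-administration and
    admission records: days of therapy (DOT), length of therapy (LOT) and
    administered defined daily doses (DDD), stratified by care level,
    referring clinic, demography and drug class, and normalised per 1000
    patient-days.  Merges readmissions within 48 hours into intensive-care
    episodes, classifies episodes by antimicrobial drug-class exposure,
    links exposure with SAPS 3 predicted and observed mortality, fits cubic
    regression-spline trends of daily consumption, and bundles the standard
    surveillance reports.  Ships a curated WHO ATC/DDD reference table for
    ICU-relevant antimicrobials and a calibrated synthetic-data generator so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    rlang,
    lubridate,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
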