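Package: clinicflow
Title: Discrete-Event Simulation of an Outpatient Post-Term Pregnancy Clinic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for capacity and patient-flow planning in a post-term
    pregnancy outpatient clinic. Service-time distributions are fitted by
    moment matching to expert-elicited bounded summaries, a discrete-event
    engine simulates one clinic day (check-in, cardiotocography connection,
    scan and disconnection, doctor consultation, check-out) under resource
    constraints, and higher-level helpers run full-factorial configuration
    experiments, search for the maximum demand each resource mix can serve
    within opening hours, and build grouped KPI report tables. A small
    module reproduces the attendance analysis from printed count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
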