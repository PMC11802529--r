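Package: pvsignal
Title: Descriptive and Disproportionality Analysis of Spontaneous Adverse
    Drug Reaction Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on spontaneous
    reporting system data: a two-level MedDRA-style PT-to-SOC dictionary,
    readers and aggregators for individual case safety reports, descriptive
    surfaces (System Organ Class report rates, top-N preferred terms,
    demographic and serious-outcome summaries), and 2x2 disproportionality
    statistics (reporting odds ratio and proportional reporting ratio with
    log-scale Wald 95% confidence intervals and case-count significance
    screening). Ships the published VigiAccess count tables for five hepatic
    anti-fibrotic agents as packaged fixtures, and a synthetic
    spontaneous-report generator with injectable drug-reaction signal
    strengths for end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
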