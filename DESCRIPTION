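Package: akiimpact
Title: Creatinine-Based AKI Ascertainment, Risk-Score Alerting and
    Controlled Before-After Impact Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates two-site, two-period acute medical admission cohorts
    with time-stamped serum creatinine series; ascertains community- and
    hospital-acquired acute kidney injury (AKI) from KDIGO creatinine
    criteria (ratio-to-baseline, rolling 48-hour rise, absolute level);
    scores admissions with a configurable clinical prediction rule and
    assigns RED/AMBER/GREEN alert states; applies study inclusion rules;
    and estimates intervention impact with contingency-table odds ratios
    (Woolf intervals), Cochran-Mantel-Haenszel tests and
    difference-in-differences logistic models with patient-level
    clustering via generalised estimating equations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
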