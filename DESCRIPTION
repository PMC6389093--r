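Package: tiaqueue
Title: Time-Dependent Weighted Triage for TIA Unit Referrals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for triaging referrals to outpatient transient ischemic
    attack (TIA) assessment units. Implements a time-dependent weighted
    triage score that combines a configurable logistic classifier for the
    probability of TIA/minor stroke with ABCD2-stratum recurrent-stroke
    risk curves, a dynamically re-ranked referral queue, and a
    discrete-event simulator of unit booking under competing triage
    policies. Includes the evaluation pipeline used to compare policies:
    calendar-day time-to-unit outcomes, 28-day right censoring,
    Kaplan-Meier estimation, Peto-Peto modified Gehan-Wilcoxon tests, and
    a six-stratum (ABCD2 risk group by diagnosis) comparison report, plus
    a reproducible synthetic referral-stream generator so the whole
    pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
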