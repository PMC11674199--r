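Package: aesiloc
Title: Level-of-Certainty Classification for Adverse Events of Special Interest
Version: 0.1.0
Authors@R:
    person("AESI Surveillance", "Tools", email = "aesiloc@example.org",
           role = c("aut", "cre"))
Description: A declarative rule engine for assigning Brighton Collaboration
    levels of diagnostic certainty (LOC 1-5) to suspected adverse events of
    special interest (AESI) from hospital surveillance line-lists. Criteria
    take tri-state values (present / absent / unknown) and case-definition
    predicates are evaluated under strong Kleene three-valued logic, so that
    missing clinical data propagates to "insufficient information" (level 4)
    rather than silently failing a case. Ships machine-readable rule sets for
    the conditions monitored in a sentinel-hospital AESI surveillance
    (Guillain-Barre syndrome, myocarditis, pericarditis, generalized
    convulsion, encephalitis, myelitis, thrombocytopenia, thrombosis and
    thromboembolism, and schema examples for further conditions), a seeded
    synthetic roster generator with per-criterion prevalence and missingness,
    a hand-authored 203-case reference roster, and descriptive summaries:
    LOC distributions, level-4 reason tabulations, criterion-prevalence and
    demographics tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
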