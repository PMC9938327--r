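Package: pcrt
Title: Pancreatic Cancer Risk Tool Questionnaire Scoring and Triage
Version: 0.1.0
Authors@R: person("pcrt", "maintainers", email = "pcrt@example.org", role = c("aut", "cre"))
Description: Implements a patient-input questionnaire data model for familial
    cancer-risk screening, a configurable point-based scoring rule with a
    genetic-counseling referral threshold, a new-onset-diabetes (ENDPAC
    criteria) triage rule, synthetic cohort simulation, and cohort-level
    summary tables with standard group-comparison tests. Ships a command-line
    interface with score, triage, simulate, and report subcommands.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
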