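Package: smbgflow
Title: Structured SMBG Pattern Analysis and Decision-Support Flowchart
Version: 0.1.0
Authors@R: person("SMBG Flow", "Maintainers", email = "maintainers@smbgflow.org",
    role = c("aut", "cre"))
Description: A rule-based pattern-management engine for structured
    self-monitoring of blood glucose (SMBG) logs. Implements a three-step
    clinical flowchart: (1) data-sufficiency gating on the quantity and
    quality of meter tests, (2) red/clear pattern detectors for
    hypoglycemia and hyperglycemia trends, time-block recurrence, and very
    low/very high excursions with clinically settable parameter ranges,
    and (3) glycemic-variability assessment (SD, CV, LBGI, HBGI) gating
    categorical therapy-action flags. Includes a seeded synthetic SMBG
    generator with oracle-verified pattern injection, period comparison,
    and a command-line interface producing JSON and text reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
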