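Package: coursefit
Title: Concordance of Antibiotic Package Sizes with Guideline Treatment Regimens
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Audits a registry of marketed oral antibiotic packages against
    guideline treatment regimens (dose, dosing frequency, duration) and
    reports, for every applicable package-regimen pair, the minimal number of
    packages needed to complete the course and the leftover units, assuming
    full adherence. Flexible dose ranges and duration intervals are resolved
    by leftover minimization; formulations scored for halving may contribute
    half units, tracked exactly. Includes a registry ingest pipeline with an
    auditable exclusion log, guideline-level and reimbursement-stratified
    aggregation, a synthetic registry/regimen generator with planted ground
    truth, a packaged reference dataset of published audit tables, and a
    command-line interface.
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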