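Package: lupuscea
Title: Cost-Utility Markov Model for Early Versus Delayed Belimumab in
    Systemic Lupus Erythematosus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A six-state monthly-cycle Markov cohort model comparing early
    and delayed initiation of intravenous belimumab in biologic-naive adults
    with clinically active systemic lupus erythematosus, from a US payer
    perspective. The package provides a validated parameter ledger with
    per-entry distributions for probabilistic sensitivity analysis, a
    life-table mortality layer adjusted by standardized mortality ratios,
    glucocorticoid-dose utility decrements, discounted cost and QALY
    accumulation, incremental cost-effectiveness ratios and net monetary
    benefit, cost-effectiveness acceptability curves, one-way deterministic
    sensitivity analysis (tornado diagrams), horizon sweeps, biosimilar
    pricing scenarios, a synthetic life-table and ledger generator, and a
    calibration routine that pins free parameters to published base-case
    totals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
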