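Package: faersig
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on FDA Adverse
    Event Reporting System (FAERS) quarterly ASCII extracts. Reads the
    "$"-delimited DEMO/DRUG/REAC/OUTC/THER/INDI tables and deleted-case
    rosters, applies the FDA-recommended deduplication rule (latest FDA_DT,
    then highest PRIMARYID per CASEID), builds a primary-suspect drug cohort
    by name matching, and computes four disproportionality statistics per
    MedDRA preferred term and system organ class: the reporting odds ratio
    (ROR), the proportional reporting ratio (PRR) with Pearson chi-squared,
    the Bayesian confidence propagation neural network information component
    (IC), and the unshrunk empirical Bayes geometric mean (EBGM), each with
    its conventional signal criterion. Also provides time-to-onset
    summaries, descriptive demographics, a deterministic synthetic FAERS
    generator with planted drug-event signals for validation, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
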