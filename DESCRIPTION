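Package: faerssignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for FAERS-style quarterly
    extract files, built around a pediatric cataract case study. Reads and
    writes the "$"-delimited quarterly ASCII tables (DEMO, DRUG, REAC, THER,
    OUTC, INDI), applies the FDA-recommended CASEID/FDA_DT/PRIMARYID
    deduplication rule, standardizes mixed-unit ages to years, defines cataract
    cases from MedDRA Preferred Term codes (broad and narrow query sets),
    harmonizes verbatim drug names to generic entities via an editable mapping
    table, and screens primary-suspect drugs with four disproportionality
    algorithms (reporting odds ratio, proportional reporting ratio with Yates
    chi-square, Bayesian confidence propagation information component, and the
    empirical Bayes geometric mean score) combined into a conservative
    consensus flag. Time-to-onset analysis covers inclusion accounting,
    interval binning, Weibull maximum-likelihood fitting with confidence
    intervals, and a two-group log-rank comparison. A synthetic-FAERS
    generator with full ground truth (planted drug-event signals, versioned
    duplicates, mixed age units, date pathologies) makes every stage testable
    without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
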