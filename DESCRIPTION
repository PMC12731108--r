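Package: burdenscan
Title: Rare-Variant Burden Testing with Variable Deleteriousness Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Case-control rare-variant burden analysis for cancer
    susceptibility gene discovery. Implements cross-cohort quality-control
    calibration on neutral variant classes (rare synonymous and in-frame
    indels), a per-gene binomial burden test with a variable
    VEST4-deleteriousness-threshold scan, label-shuffling permutation
    correction with an exact hypergeometric oracle, pooled-rate relative
    risk, gene-set burden tests with oncogene loss-of-function exclusion,
    replication-mode phenotype assignment from ICD-10 codes, a synthetic
    cohort generator for calibration and operating-characteristic studies,
    and QQ/lollipop reporting data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
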