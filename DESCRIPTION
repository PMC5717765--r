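Package: mrkit
Title: Two-Sample Mendelian Randomisation with GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-sample Mendelian randomisation using GWAS
    summary statistics. Reads and harmonises per-variant association
    tables onto a common effect allele (including palindromic-variant
    handling, strand complements, proxy substitution and LD pruning),
    estimates causal effects with the inverse-variance weighted,
    weighted median, penalised weighted median and MR-Egger methods,
    and provides sensitivity diagnostics (leave-one-out, instrument
    strength F statistics, variant-exclusion filters). Includes a
    synthetic summary-statistic generator with known causal effect and
    controllable pleiotropy for validation, and a config-driven
    multi-risk-factor pipeline with Bonferroni significance
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
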