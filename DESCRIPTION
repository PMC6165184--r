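Package: summaryMR
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample Mendelian randomization with GWAS
    summary statistics: reading and validating per-SNP association
    tables, proxy substitution, unit conversion, allele harmonization,
    and causal-effect estimation by the inverse-variance weighted,
    weighted median (with parametric bootstrap), and MR-Egger methods,
    together with Cochran's Q heterogeneity, leave-one-out sensitivity
    analysis, forest-table export, and a summary-statistic simulator
    for calibration studies. Ships a worked example estimating the
    effect of serum parathyroid hormone and serum 25-hydroxyvitamin D
    on Alzheimer's disease risk.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
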