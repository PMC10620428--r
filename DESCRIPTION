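Package: dtmr
Title: Drug-Target Mendelian Randomisation from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomisation toolkit for drug-target (cis)
    analyses built on GWAS summary statistics. Selects genetic instruments
    from gene, promoter and enhancer regions of a drug-target gene by
    Bonferroni thresholding, greedy LD clumping and palindrome exclusion;
    harmonises exposure and outcome associations to a shared effect-allele
    orientation; and estimates causal effects with inverse-variance-weighted
    random-effects, Wald ratio, weighted median, weighted mode, MR-Egger,
    MR-RAPS and MR-PRESSO estimators, together with Cochran's Q, leave-one-out,
    Cook's distance and scatter/funnel diagnostics. Includes a synthetic
    summary-statistics generator with configurable pleiotropy regimes,
    palindromic variants and block LD for end-to-end testing without external
    GWAS downloads, and a pipeline that emits forest-style report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
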