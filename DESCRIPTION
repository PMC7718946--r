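Package: mycstrat
Title: MYC-Activity Stratification of Pancreatic Tumor Transcriptomes and
    Drug-Vulnerability Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies MYC-hyperactive pancreatic tumors and cell lines from
    log2 expression matrices by hierarchical clustering on multiple MYC
    target-gene signatures with a consensus (intersection) call, and links MYC
    activity to drug vulnerability. Includes a gene set enrichment analysis
    engine (weighted Kolmogorov-Smirnov running-sum statistic, phenotype or
    gene-set permutation null, normalized enrichment scores and tail-ratio FDR
    q-values), single-dose drug-screen hit calling by the response-ratio rule,
    four-parameter logistic dose-response fitting with GI50 and AUC,
    sensitivity-quartile phenotype construction, Kaplan-Meier and log-rank
    survival statistics, an exact two-sided Fisher test by hypergeometric
    enumeration, and delta-delta-Ct quantification. A synthetic-data module
    generates cohorts, screens and dose-response series with planted structure
    so the full pipeline is testable without external consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival,
    fgsea
Config/testthat/edition: 3
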