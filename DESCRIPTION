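Package: methnetprog
Title: Rank-Based Co-Methylation Networks and Hub-Based Prognostic Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds rank-based DNA co-methylation interaction networks from
    beta-value matrices (each CpG site keeps its k most correlated partners by
    Spearman rank correlation), diagnoses scale-free topology by log-log
    power-law fits of the degree distribution, selects high-degree hub sites,
    screens hubs for survival association with univariate Cox
    proportional-hazards regression, scores patients with a GGI-style
    sum-of-risk-sites score, stratifies them into good- and bad-outcome halves,
    and quantifies the split-half stability of prognostic feature selection
    with hypergeometric overlap tests. Includes a synthetic multi-omics data
    generator with ground-truth driver sites so the whole pipeline is testable
    without cohort downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
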