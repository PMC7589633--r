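Package: dysFFL
Title: Dysregulated TF-miRNA Feed-Forward Loops from Paired Expression
    Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies transcription-factor / microRNA / target-gene
    feed-forward loops (FFLs) whose joint differential expression and
    differential coexpression distinguish two paired experimental
    conditions. Provides typed regulatory-network input/output, quantile
    normalisation and empirical-Bayes moderated paired t differential
    expression, motif enumeration and classification (TF-FFL, miRNA-FFL,
    FB-FFL), inverse-normal node and Fisher-z differential-coexpression
    edge scoring with a permutation null, body-system subnetwork assembly
    and sharing analysis, hypergeometric gene-set enrichment, rank-shift
    Wilcoxon concordance tests against external differential-expression
    lists, signature-reversal drug screening, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
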