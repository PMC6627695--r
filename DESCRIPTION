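Package: miRGstab
Title: Reference-Gene Stability Ranking for qRT-PCR miRNA Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects stable reference genes (normalizers) from qRT-PCR
    quantification-cycle (Ct/Crt) panels of miRNAs and small RNAs measured
    across grouped samples, such as chondrocyte populations from developing
    cartilage. Provides a CtExperiment container built on
    SummarizedExperiment, complete-detection filtering, and four
    gold-standard stability estimators (BestKeeper dispersion, geNorm
    stepwise M value, NormFinder intra/intergroup variance model, and the
    comparative delta-Ct method), combined into a geometric-mean consensus
    ranking. Downstream tools quantify how the choice of reference gene
    changes normalized expression, group comparisons with Grubbs outlier
    screening, gene-gene correlation, and correlation-distance
    average-linkage clustering. A synthetic-data generator with planted
    stable, noisy, and group-shifted genes supports end-to-end validation
    and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: GeneExpression, Normalization, qPCR, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
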