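Package: tripletCis
Title: Orphan CpG Island-Enhancer-Gene Triplet Cis-Regulatory Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers cis-regulatory relationships among orphan CpG islands
    (oCGIs), enhancers and genes from DNA methylation and expression data.
    Defines oCGIs by expanding and merging CpG islands and removing
    promoter/enhancer overlaps, QC-filters and KNN-imputes probe-level beta
    matrices, aggregates methylation to regions with hypo/hemi/hyper state
    calls, pairs elements with genes inside shared topologically associating
    domains, screens pairs by permutation-tested mutual information with FDR
    control, assigns each oCGI-enhancer-gene triplet one of nine Bayesian
    network regulatory structures by AIC with conditional-independence
    validation, applies cluster-direction concordance filtering, and computes
    per-sample cis scores. A synthetic-data generator with known ground truth
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, GeneRegulation, NetworkInference
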