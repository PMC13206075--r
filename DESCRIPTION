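Package: dedtarget
Title: Consensus Transcriptomic Target Discovery and Perturbation
    Concordance for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for computational drug-target discovery
    from heterogeneous transcriptomic disease models: per-dataset
    differential expression with median-of-ratios normalization and
    moderated fold changes, pre-ranked gene-set enrichment with
    leading-edge extraction, cross-dataset consensus pathway and core
    leading-edge gene nomination, intersection with predicted drug targets
    and docking-affinity triage, and validation of candidate targets by
    concordance between simulated single-gene knockdown profiles and the
    drug perturbation profile (top-fraction Pearson correlation against a
    random-gene null, rank-sum testing, and pathway-level AUROC). A
    negative-binomial multi-dataset simulator with planted pathway signals
    makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
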