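Package: idrscape
Title: Intrinsic Disorder Landscape Analysis for Transcription Factor Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Domain-partitioned analysis of intrinsic disorder in protein
    families such as the AP2/ERF transcription factors: amino-acid
    compositional profiling against a fully-structured-protein baseline with
    bootstrap confidence intervals, charge-hydropathy (CH) and cumulative
    distribution function (CDF) binary disorder classifiers combined into
    CH-CDF phase space, per-residue disorder tracks and IDAA percentage
    statistics, CAST-style iterative low-complexity masking with
    region-partitioned LCAA summaries, molecular recognition feature (MoRF)
    candidate detection with subgroup-level conserved-MoRF calling and
    naming, phosphosite fraction statistics by residue type and region, and
    a neighbour-joining subgroup tree with bootstrap support. A synthetic
    family generator with machine-readable ground truth makes every stage
    testable without external predictors or downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
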