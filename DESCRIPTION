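Package: genorisk
Title: Genomic Risk Profiling of DNA Damage Checkpoint and Repair Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tissue expression profiling and disease genomic-risk scoring for a
    curated 68-gene panel of DNA damage checkpoint factors (DDCFs) and DNA
    damage repair factors (DDRFs). Normalizes expressed-sequence-tag (EST)
    counts to transcripts per million, classifies gene-tissue expression into
    high/low/absent calls with tissue "variety" tiers, calls up/down modulation
    from case-versus-control fold-change tables, computes a genomic-risk index
    with a three-group classification, analyzes cross-disease overlap of
    modulated genes, and classifies genes as hypo-, hyper- or non-methylation
    regulated from tissue SAM/SAH correlation. Ships a seeded synthetic-data
    generator that emulates the EST, microarray-contrast and tissue-methylation
    inputs with planted ground truth, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
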