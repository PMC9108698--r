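Package: trbserial
Title: Serial Analysis of T-Cell Receptor Beta-Chain Repertoires
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal analysis of T-cell receptor beta-chain (TRB) CDR3
    repertoires from AIRR-seq rearrangement tables. Provides readers and
    writers for immunoSEQ-style and AIRR rearrangement formats, depth
    normalization by repeated downsampling, per-repertoire diversity
    statistics (clonality, Gini coefficient, TRB sequence production
    efficiency, CDR3 length spectra, cumulative top-N clone frequencies),
    pairwise repertoire similarity, edit-distance-1 CDR3 network topology
    with pooled degree distributions, clonotype annotation against VDJdb and
    McPAS-TCR style databases with MHC-restriction filtering, specificity
    group propagation, longitudinal clone tracking around antiretroviral
    therapy initiation, candidate public clonotype discovery, and rank-based
    group comparisons with Holm-Bonferroni correction. A synthetic cohort
    generator emulates the statistical structure of pre-treatment,
    post-treatment, and control repertoires so the full pipeline can be run
    and validated without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    mgcv,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
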