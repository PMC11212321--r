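Package: ClonoTRB
Title: Simulation and Clonality Analysis of TRB CDR3 Immune Repertoires
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for T-cell receptor beta-chain (TRB) CDR3 repertoire
    profiling: a ground-truth V(D)J read simulator with unique molecular
    identifiers (UMIs), a UMI-consensus read-to-clonotype assembler with
    germline V/J assignment, CDR3 junction extraction and productivity
    filtering, per-repertoire clonality statistics (inverse Simpson,
    Shannon-Weaver, Berger-Parker, segment usage, CDR3 length and motif
    profiles, expansion profiles), and comparative analyses across
    repertoires (overlap and Venn decomposition, Baroni-Urbani & Buser
    similarity, clone tracking, emerging-clone detection and
    Kolmogorov-Smirnov comparison of dominant clonotypes), tied together by
    a deterministic end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    BiocGenerics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
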