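Package: bhlhscan
Title: Genome-Wide Identification and Classification of bHLH Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scans genomic contigs for regions coding basic helix-loop-helix
    (bHLH) motifs via six-frame translated local alignment against reference
    motif sets, accepts candidates by a 19-conserved-site statistic, places
    accepted motifs into a fixed reference alignment, assigns each candidate
    to an orthologous family through tiered monophyly and bootstrap-support
    rules on neighbor-joining and parsimony trees, and summarizes the intron
    architecture of the recovered gene models. Ships a transcription of the
    ponerine ant bHLH repertoire as an in-package fixture and a synthetic
    genome generator with known truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
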