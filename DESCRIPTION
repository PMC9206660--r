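Package: pepseq
Title: Pooled Self-Editing Screens for Peptide Modulators of Prime Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled peptide self-editing sequencing screens, in
    which a library of tiled peptide-prime-editor fusions each edits a fixed
    target site adjacent to its own coding sequence, so that paired-end
    amplicon sequencing links peptide identity to editing outcome. Provides
    tiled library design with phosphomimetic variants and codon-level
    encoding, a ground-truthed paired-end FASTQ simulator, read
    demultiplexing by exact nucleotide prefix, Needleman-Wunsch allele
    classification with quality-aware mismatch and indel filtering,
    beta-binomial maximum-likelihood inference of per-peptide editing
    effects with control-normalized hit calling, and an additive linear
    model of dual-peptide fusion effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
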