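Package: foldannot
Title: Structure-Informed Functional Annotation of Phage Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of FoldSeek structural-similarity searches for
    the annotation of phage proteins of unknown function ("viral dark
    matter"). Provides readers for FoldSeek 15-column hit tables, predicted
    structures carrying per-residue pLDDT in the B-factor field, A3M multiple
    sequence alignments, MMseqs2 cluster tables and annotation/identifier
    mapping tables; dataset curation (label and size filters, deduplication,
    the "truly unannotated" split); structure-prediction quality control
    (mean pLDDT, MSA depth, depth tipping-point contrasts, binned and
    resampled length correlations); two-stage hit filtering (E-value
    significance, then alignment-quality); best-hit, best-annotated-hit,
    UniProt-supplemented and three-tiered annotation-transfer strategies with
    multi-database combination and complementarity accounting; and a
    synthetic-data generator with an exact ground-truth manifest so the whole
    pipeline can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
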