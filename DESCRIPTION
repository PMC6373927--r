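Package: samforge
Title: Single-Pass Preparation of SAM Files for Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A phase-structured, single-pass engine for preparing sequence
    alignment/map (SAM) files ahead of variant calling. Merges the standard
    preparation steps -- read filtering (unmapped reads, BED target regions),
    coordinate and queryname sorting, PCR and optical duplicate marking with
    Picard-compatible semantics, duplication metrics with library-size
    estimation, and base quality score recalibration (tabulation and
    application with read-group/reported-quality/cycle/context covariates) --
    into a single traversal of the input. Offers an in-memory mode and a
    split-by-region scatter/gather mode that produce byte-identical results,
    a deterministic mode for exact output comparison, converters for FASTA
    and VCF known-sites resources, and a seeded synthetic data generator
    with ground-truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
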