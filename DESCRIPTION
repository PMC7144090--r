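Package: blobr
Title: Taxon-Annotated GC-Coverage Datasets for Genome Assembly Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Build, validate and filter per-contig assembly QC datasets
    ('BlobDir' directories of JSON documents) from assembly FASTA files, read
    alignments, tabular sequence-similarity hits, NCBI-style taxonomy dumps and
    BUSCO tables; assign per-contig taxonomy with bitscore-sum taxrules
    (bestsum, bestsumorder); encode filters as reproducible query strings; and
    compute the statistics behind taxon-annotated GC-coverage blob plots, kite
    summaries, cumulative span curves, snail plots and filter-aware BUSCO
    summaries, with deterministic SVG export. Includes a seeded synthetic-data
    generator (mixed host/contaminant assemblies with planted truth) used
    throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
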