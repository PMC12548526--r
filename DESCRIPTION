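Package: annodex
Title: Model-Aware Indexing and Fast Querying of GFF3 Genome Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a compact binary index bundle over GFF3 genome annotation
    files (feature hierarchy, annotation-block byte offsets, attribute value
    maps, seqid table, and serialized augmented interval trees) and serves
    fast queries against the original file: identifier-based extraction of
    complete annotation blocks (gene models), exact and fuzzy attribute
    search, BED-driven region intersection via interval-tree pruning, and
    exact coverage breadth and depth profiling of annotated targets from
    SAM/BAM alignments using interval merging, two-pointer sweeps, and
    slice partitioning. Includes deterministic synthetic generators for
    GFF3, BED, and SAM fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    digest,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    parallel,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
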