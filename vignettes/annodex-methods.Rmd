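---
title: "annodex: indexing model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{annodex: indexing model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annodex)
```

`annodex` answers identifier-, attribute-, and region-based queries against
GFF3 annotation files, and profiles alignment coverage over annotated
targets, by building a small binary index once and thereafter reading only
the byte ranges a query needs from the untouched source file. This vignette
explains the data model, the algorithms, the tunable parameters, and the
places where the design was genuinely open — and what the package chose
there and why.

## The annotation model

A GFF3 file is a sequence of 9-column feature lines whose `ID`/`Parent`
attributes encode a forest: parentless features (genes, standalone
elements) are roots, and a root together with all its descendants is an
**annotation block** — the minimal biologically coherent unit (a complete
gene model). Blocks, not individual lines, are the unit of extraction and
of region retrieval: a query that touches any part of a model gets the
whole model back, byte-identical to the source.

Assumptions inherited from the input format:

- Coordinates are 1-based inclusive and stay that way internally; BED input
  (0-based half-open) is converted at the parsing boundary, so
  `chr1 99 200` becomes `(chr1, 100, 200)`.
- Input is assumed well-formed; validation is limited to column count and
  coordinate sanity (`1 ≤ start ≤ end`). Malformed lines fail with their
  line number. A `##FASTA` directive terminates feature parsing.
- Hierarchy is assumed to be a forest. `Parent` references to undefined IDs
  and parent cycles are hard errors.

Three tolerant rules handle real-file sloppiness deterministically rather
than rejecting the file:

- **Multiple `Parent` values**: the first listed parent decides block
  membership; if the listed parents resolve to different roots, a warning
  names the feature. A deterministic rule was preferred over rejection
  because multi-parent features (shared exons) are common.
- **Repeated IDs**: lines sharing an ID with the same type and parent are
  one discontinuous feature (legal GFF3, typical for multi-segment CDS) and
  are silently treated as one feature with several lines. Conflicting
  redefinitions warn, and the last definition wins for `Parent` resolution.
- **Cross-seqid members**: a member on a different seqid than its root
  stays in the root's block, but its interval is indexed under its own
  seqid (pointing at the same block), so region queries find it where it
  lies.

Features without an `ID` (most exons) are numbered and block-assigned but
cannot be looked up by string — consistent with GFF3, which only requires
`ID` on features that are referenced.

Interleaved gene models (lines of two models alternating in the file) are
supported: a block's byte extent is stored as the minimal list of maximal
contiguous byte runs covering exactly its member lines, so extraction
reproduces exactly the member lines and nothing else. The format itself
does not define what a "block" means for interleaved models; the
multi-range representation is this package's resolution.

## The index bundle

Eight files, one per table, are written next to the source. Separate files
(rather than one container) let each operation open only what it needs:
extraction touches `.fts/.prt/.gof`, attribute search adds `.atn/.a2f`,
region intersection uses `.gof/.prt/.sqs/.rit/.rix`. The tests assert these
subsets through a load-audit hook recorded by the bundle loader.

Layout choices, fixed for bit-exact portability: little-endian throughout;
feature/block numbers and table positions unsigned 32-bit (feature counts
beyond 2³¹ are refused with a capacity error); byte offsets, coordinates
and counts unsigned 64-bit; strings length-prefixed raw bytes; feature
numbers 0-based on disk (0..n−1 in appearance order) and 1-based in R
memory, converted only at the serialization boundary. 64-bit values are
held in R doubles, exact below 2⁵³ — far beyond any real file size or
genome coordinate.

Every file starts with a header carrying the source file's size and its
**xxHash64** checksum, plus the hash algorithm id, so an index read against
a modified source fails with a stale-index error instead of silently
returning wrong byte ranges. xxHash64 was chosen as a widely available,
fast, 64-bit non-cryptographic hash (via the `digest` package); recording
the algorithm id means a future algorithm change fails loudly rather than
colliding silently. Building twice from the same source yields
byte-identical index files; the attribute value table is sorted by raw
bytes (locale-independent radix order) to keep this determinism.

The `.sqs` file holds the seqid string table in order of first appearance.
Its exact role is the one piece of the layout that is an interpretation:
region queries need a stable seqid numbering shared by `.gof` and `.rix`,
and the seqid table is the natural carrier.

## Interval trees

Per seqid, block spans (per-seqid min/max over members) go into a static
augmented interval tree: intervals sorted by `(start, end, block)` — the
tie-break makes layout and query output fully deterministic — and a
balanced BST built by recursive median split, so depth ≤ ⌈log₂(N+1)⌉ with
no rebalancing machinery. Nodes live in a flat array in in-order
(= sorted) sequence, which is also the on-disk `.rit` layout; `.rix`
records each seqid's byte range so one seqid's tree is read alone.

Each node stores `max_end`, the maximum endpoint in its subtree, computed
bottom-up. A query `[qs, qe]` (overlap predicate `start ≤ qe ∧ end ≥ qs`)
descends into a subtree only when its `max_end ≥ qs` and skips the right
child once `node.start > qe`. The tests assert the operational visit bound
`visits ≤ 2(⌊log₂N⌋+1) + 4k` for every tested query (N up to 10⁵), and —
the module's principal property — exact agreement of the hit set with a
linear scan over all intervals on randomized instances.

One interval per block is indexed, not one per feature: region retrieval
returns whole models through the block byte map, and feature-level
refinement (`mode = "feature"`) re-parses the member lines of hit blocks
and keeps those whose own span overlaps a query. The default mode is
`block` — model awareness is the point of indexing blocks — and the
feature mode never clips coordinates, so output lines stay verbatim.
Queries on seqids absent from the index return empty results, not errors:
asking about an unannotated contig is legal.

## Attribute search

At build time the requested attribute keys (default `ID` and `Name`,
changeable via `attribute_keys`/`--attr-keys`) are collected into a sorted
value table mapping each `(key, value)` to its feature numbers. Exact
search is a byte-equality binary search; fuzzy search is a
case-insensitive substring scan. "Fuzzy" is not a defined term in the
source format; substring matching is the minimal defensible reading, kept
deliberately simple (edit-distance or regex matching would hide a
complexity cliff behind a flag). Exact matches are by construction a
subset of fuzzy matches of the same pattern, and the tests assert it.
Searching a key that was not indexed is an error that tells the user to
re-index with that key, never a silent empty result.

## Coverage breadth and depth

Alignments (SAM/BAM, read via Rsamtools) become reference-space intervals:
CIGAR `M`/`=`/`X`/`D` consume reference, `N` splits the record into
multiple intervals, `I`/`S`/`H`/`P` consume nothing. Two conventions are
explicit parameters because tools disagree:

- `include_deletions = TRUE` (default): `D` bases count as covered —
  reference-span semantics. A flag flips them to uncovered for parity with
  per-base pileup tools.
- Merging treats bookended intervals (`end + 1 == next start`) as one run,
  so a target fully tiled by abutting reads reaches breadth exactly 1.

Default record filters: unmapped, secondary (0x100), and supplementary
(0x800) records are excluded; duplicates (0x400) are kept unless
`drop_duplicates = TRUE`. These are deterministic, documented defaults for
a question on which the literature is silent.

Definitions (stated because they are often left implicit): **breadth** of a
target is `covered_bases / length`, where a base is covered if ≥ 1 kept
alignment overlaps it; **depth** is the per-base count of overlapping
alignments, reported as the per-target sum and mean (`depth_sum / length`),
with an optional per-target histogram of bases at each integer depth.

Breadth is computed by merging the slice's intervals and sweeping targets
and merged runs with two co-linear pointers (linear in targets + intervals
+ overlaps). Depth uses a difference array over the slice followed by one
prefix sum, so a target's `depth_sum` is a difference of two prefix values
— exact integer arithmetic throughout, no floating accumulation.

**Slicing**: targets are clustered by overlap and clusters packed greedily
into slices of at most `max_slice` bases; a cut never falls inside a
target, and a single cluster longer than `max_slice` stretches its slice
rather than splitting a target. Every alignment interval is assigned to
every slice it overlaps (clipped to the slice for the difference array,
which is exact because each target lies wholly inside one slice). Slices
are independent work units: with `workers > 1` they are processed with
`parallel::mclapply` and reassembled in target input order. The tests
assert byte-identical rendered output across slice sizes {1 kb, 10 kb, ∞},
1 vs 4 workers, and coordinate-sorted vs shuffled input — the
reconciliation contract that makes the parallelism trustworthy. Intervals
are fully sorted after reading precisely so that sorted and unsorted input
are indistinguishable downstream.

Targets come either from a BED file or from the annotation itself
(`target_type`, default `gene`): the chosen type's features are recovered
by re-parsing the byte ranges of their blocks, so coordinates and IDs are
read from the source bytes, not from a second serialization.

## Synthetic data: what it does and does not emulate

All tests and the acceptance script run on generated data; the generators
are pure functions of their parameters and seed (byte-identical output,
caller's RNG state untouched).

`generate_gff3` emulates the structural features that stress this package:
nested gene → mRNA → exon/CDS models, one or two transcripts per gene
(`multi_transcript_p = 0.3`), exons without IDs, discontinuous CDS sharing
an ID, mixed-case `Name` values for fuzzy search, and line-wise
interleaving of a fraction of adjacent gene pairs
(`interleave_fraction = 0.1` by default; raised in tests that target
multi-range blocks). Defaults — gene lengths 0.5–5 kb, two seqids of 1 Mb —
give compact files with realistic nesting depth. It does **not** emulate:
attribute zoos of real annotations (only `ID`/`Parent`/`Name`), overlapping
gene clusters on opposite strands, trans-splicing, or pathological header
dialects. Passing tests therefore demonstrate correctness of hierarchy,
byte-range, and interval logic — not robustness to every real-world GFF
quirk.

`generate_alignments` writes primary mapped SAM records with `M` or
`M N M` CIGARs (`spliced_p = 0.2`), which exercises exactly the reference-
consumption semantics coverage depends on; it does not simulate errors,
quality strings, pairing, or clipping (clipping and flag filters are
covered by small hand-written SAM records in the tests). `generate_bed`
mirrors the random-bin style of region benchmarking at desk scale.

Problem sizes in the test suite and acceptance script were chosen to finish
comfortably on one CPU while staying in the regime the data structures are
built for: interval-tree checks use up to 10⁴ intervals and 10³ 20-kb
queries per fixture across 20 fixtures (k ≪ N, the annotation-like density
where pruning matters); coverage checks use 10³ targets × 10⁴ reads per
fixture across 20 fixtures, verified target-by-target against a per-base
counting array.

## Numerical and degenerate-input choices

- All quantities are integers or exact integer ratios; there are no
  tolerances anywhere — every comparison in the tests is exact equality.
- Empty inputs are valid everywhere: a feature-less GFF builds a valid
  bundle whose queries all return empty; an empty interval set builds an
  empty tree; zero targets or zero alignments yield zero rows or zero
  coverage, with exit code 0 from the CLI.
- Zero-length BED intervals (`start == end` in 0-based half-open terms) are
  rejected as malformed rather than silently becoming 1-bp queries.
- Ties in the interval tree are broken by `(end, block)`; block emission is
  always in file order; shuffling query-region input order cannot change a
  single output byte.
- Unknown extraction IDs warn and are skipped; only if *all* IDs are
  unknown (or `strict = TRUE`) does the call fail. This matches batch
  usage, where one stale ID should not abort a 10⁵-ID extraction.

## Known limitations

- GFF3 only: no GTF/GFF2 dialect support.
- The `##FASTA` section is honored as a parsing boundary only; sequence
  extraction is out of scope.
- Fuzzy search is substring-based; no regex or edit-distance matching.
- Intersection reports overlap of ≥ 1 bp; there is no minimum-overlap
  fraction, no strand-aware mode, and no coordinate clipping.
- Indices are single-writer: concurrent builds over the same source are
  not coordinated.
- The per-process bundle cache trusts the staleness check performed at
  load time; a file modified *during* a process's lifetime after a load is
  not re-checked until `flush_bundle_cache()` or a new process.
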