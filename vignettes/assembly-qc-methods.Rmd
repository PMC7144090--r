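---
title: "Methods: taxon-annotated GC-coverage datasets for assembly QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxon-annotated GC-coverage datasets for assembly QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blobr)
```

## The screening model

Contaminant and cobiont screening in `blobr` rests on three weak, largely
independent per-contig signals:

1. **GC proportion.** Genomes differ in mean base composition, and
   intra-genomic GC is usually unimodal around that mean, so contigs from a
   second organism often form a second mode on the GC axis.
2. **Coverage.** Contigs from one genome share the stoichiometry of their
   source DNA, so read coverage is roughly constant within a genome but
   often very different between target and contaminant (organelles,
   collapsed repeats, sex chromosomes and uncollapsed haplotypes are the
   systematic exceptions).
3. **Taxonomic annotation.** Local-alignment hits against annotated
   databases give each contig a tentative taxon.

None of the three is reliable alone — databases are mis-annotated, coverage
is confounded, GC overlaps — which is why every view in the package plots
the first two annotated by the third, and why all three are stored
side-by-side in one dataset.

## The BlobDir dataset

A dataset is a directory of JSON documents: `meta.json` collates the
metadata for every field, so basic information can be read without touching
any values, and each field lives in its own `<field_id>.json` with one entry
per contig. Fields are typed generically — identifier, variable (numeric
with a `[min, max]` metadata range), category (integer indices into a `keys`
label list; indices are 0-based on disk and in memory), array and
multiarray — so new analyses can be attached without format changes.

Numbers are serialised at 17 significant digits, which is sufficient for a
write/read cycle to reproduce IEEE doubles exactly; the round-trip identity
is asserted in the test suite on randomly generated datasets.

Design decisions worth recording:

* Variable metadata ranges are **always recomputed** when a field is added
  or a dataset filtered, never trusted from input. This keeps the validator
  symmetric: a range violation can only mean the files were edited.
* `no-hit` is an ordinary category key, not a sentinel, so the common
  recipe "exclude key `no-hit` at phylum" is just a category filter.
* The validator treats structural problems (missing files, orphan files,
  length mismatches, out-of-range indices, uncovered ranges, wrong
  datatypes) as errors, and display-hint oddities (an unknown scale hint) as
  warnings. A dataset is valid iff it has no error-severity issues.
* JSON-schema documents for the two document shapes ship under
  `inst/schemas/`; the validator itself applies the equivalent checks
  dynamically in R (several of them — range coverage, index bounds, length
  cross-checks — depend on other files and are outside what a static schema
  can express).

## Ingest conventions

**GC and N.** `gc = (G + C) / (A + C + G + T)` case-insensitively;
`n = N / length`. Ambiguity codes other than N count toward length but are
excluded from the GC denominator. The rationale is that N-padded scaffolds
should keep a meaningful GC while the N proportion is tracked separately;
the consequence, asserted as a property test, is that the GC of a
concatenation is the unambiguous-base-weighted mean of its parts.

**Coverage.** Read coverage counts mapped, primary, non-supplementary
alignment records. Base coverage sums reference-consuming aligned bases
(CIGAR M, `=`, X; deletions excluded, since no read base covers them) and
divides by contig length. Read coverage is reported as a raw count, not
normalised — the two libraries of a coverage-vs-coverage plot are easier to
reason about in raw units. SAM is the reference dialect in tests; BAM goes
through the same entry point (Rsamtools/GenomicAlignments decode both).

**Taxrules.** Hits are mapped to taxon names at each of the eight standard
major ranks (superkingdom, kingdom, phylum, class, order, family, genus,
species) by walking taxdump parent links; a rank with no ancestor maps to
`undefined`, and a cycle or broken link is an error. Per contig and rank,
bitscores are summed per taxon; the winner is the argmax with ties broken to
the lexicographically smallest name (determinism across platforms), and the
c-index is the count of positively-scoring taxa minus one, 0 for hitless
contigs. `bestsumorder` falls back **per contig**, not per dataset: each
contig uses the first database in priority order that produced at least one
hit for it. Self-hit exclusion (e.g. removing the query genus when screening
public assemblies against the databases they came from) is modelled as a
taxid-set filter applied to hits before the taxrule.

**Chunking.** Contigs strictly longer than the 100 kb threshold are split
into `min(ceiling(length / 100000), 10)` contiguous chunks before search, so
the taxonomy of a long contig is not decided by one region. Chunk lengths
are near-equal (they differ by at most one base) rather than fixed-size with
a remainder — a remainder chunk can be arbitrarily short, and short chunks
produce noisy hits. Merging shifts hit coordinates by the chunk offset and
leaves bitscores untouched, so per-contig summed scores are exactly
preserved, which the suite asserts.

**Subsampling.** The proportion of reads to keep for a target maximum
coverage is `min(1, max_cov * span / total_read_bases)` with `max_cov`
defaulting to 100.

## Filters and reproducibility

Filters are a conjunction: variable ranges (inclusive at both ends, so a
published threshold like "coverage <= 0.01" is expressible exactly),
category key sets (exclude by default — the dominant use case is removing
`no-hit` or contaminant labels — with include mode explicit), and
identifier lists applied last. The query-string grammar
(`field--Min=`, `--Max=`, `--Inv=true`, `--Keys=[in:]a,b`) is emitted in a
canonical order (field ids lexicographic; suffixes Min, Max, Inv, Keys) so
encodings are byte-stable; `parse(encode(p)) == p` is a property test over
random parameter sets. Identifier lists are deliberately file-borne (the
exported JSON list document), never URL-borne: selections can contain
hundreds of thousands of ids. Filtering to an empty dataset is refused
rather than silently writing an empty artifact.

The same mask drives the dataset, FASTA, hit-table, BUSCO-table and SAM
subsetting, and the suite asserts the retained identifier sets agree across
all surfaces.

## View statistics

* **Binning.** Default axes are GC (linear, domain [0, 1]) against coverage
  (log10, values clamped at a 0.01 floor — the conventional coverage floor
  below which a contig is treated as unsupported). Default resolution is 30
  divisions per axis. Bin index is `floor((t(v) - lo)/(hi - lo) * res)` with
  edge clamping; the upper domain edge belongs to the last bin. Square sides
  are `scale(span) / scale(max cell span)` with sqrt scaling by default
  (linear and log selectable; log uses `log10(1 + s)` so a span of 1 does
  not vanish). Normalisation is against the global busiest cell, not
  per-category, so sides are comparable across the plot. Within a cell,
  categories render largest-first as concentric squares. Hexagonal binning
  is available under the same span-partition contract (cells are the Voronoi
  regions of an offset hexagonal lattice).
* **Kites.** All kite statistics are computed in transformed plot
  coordinates with contig lengths as weights, so the drawn regression angle
  matches the log axes it is drawn on. The weighted median is the smallest
  value whose cumulative weight reaches half the total (no interpolation —
  deterministic, and always an observed value). Extents are the weighted
  mean ±2 SD on each axis. A single-member category (or one with zero x
  variance) reports SD 0 and slope 0 by convention. Kites are drawn as ±2σ,
  reading the convention as full extents rather than a 2σ-long line.
* **Cumulative and Nx.** Lengths are sorted descending and accumulated; the
  Nx statistic is the length at which the cumulative span first reaches the
  fraction. Per-category curves stack in descending span order.
* **Snail.** 1000 cumulative segments along the descending-sorted
  concatenation; each segment reports the length of the contig containing
  its end position and the min/weighted-mean/max GC of the contigs
  overlapping the slice (the exact ring contents are a design choice; the
  slice-overlap rule keeps every segment non-empty and the length ring
  non-increasing).
* **BUSCO.** Counts are recomputed under the active mask: an ortholog id is
  Duplicated when ≥2 retained contigs carry it complete, Complete with
  exactly one, Fragmented when only fragments survive, Missing otherwise —
  so counts always sum to the lineage total, under any mask.
* **Presentation thresholds.** Individual-circle views are sensible below
  100,000 contigs; above that only binned views are exposed, and above
  1,000,000 contigs the default view filters `no-hit` contigs.
* **SVG.** Renderings are plain-text SVG 1.1 assembled with fixed element
  order and fixed number formatting, so the same input always yields
  byte-identical output — required for golden-file tests and honest
  "regenerate this figure" claims.

## The synthetic-data generator

The generator emulates exactly the features the toolkit reasons about:
per-component GC means (i.i.d. bases, per-contig GC drawn around the
component mean), uniform target coverage hit by exact read counts of
error-free fully aligned reads, log-normal contig lengths, and hit tables
whose true-taxid hits outscore noisy ones. The standard two-component
condition used in tests and in the acceptance script is a host at GC 0.35
and 30× coverage against a proteobacterial contaminant at GC 0.55 and 5×,
hit noise 0 — separations chosen to mirror the host/γ-proteobacterial
contrasts typical of published screens. Everything is a pure function of
(spec, seed).

What it does **not** model, and what passing tests therefore do not show:
repeats and heterozygosity (no collapsed-duplication coverage artifacts),
read errors and indels (coverage recovery is exact by construction),
paired-end structure, organelle stoichiometry, and database mis-annotation
beyond uniform taxid noise. Perfect precision/recall on the fixture
demonstrates the correctness of the plumbing — taxrule arithmetic, filters,
binning — not the real-world separability of any particular contaminant.

Problem sizes: the default fixture is 85 contigs (~140 kb span, ~36,000
alignment records); the taxrule oracle suite runs 200 randomised hit sets
over 6 contigs and 2 databases; statistic oracles use 100 random vectors of
up to 50 lengths. These sizes make the full suite and the acceptance script
a matter of a couple of minutes while still exercising every code path;
all statistics are O(n) or O(n log n), so nothing qualitative changes at
assembly scale.

## Numerical and degenerate-input choices

* Weighted-moment implementations are straight accumulation formulas; the
  suite requires agreement with loop-based oracles to 1e-9 relative.
* `summarize_percent` rounds half-up (not banker's rounding), matching how
  published percentages are conventionally reported.
* Degenerate inputs are errors, not silent defaults: empty identifier sets,
  empty filtered results, empty length vectors for Nx, zero totals for
  percentages, non-positive subsampling inputs, axis domains with
  `lo >= hi`.
* Query-string numbers are emitted with the shortest decimal representation
  that re-parses to the same double.

## Known limitations

* The on-disk metadata key naming is self-consistent but not claimed
  byte-compatible with any external viewer; likewise the query-string
  grammar is a faithful dialect, not a pinned external format.
* Read-file (FASTQ) subsetting by mapped-read identity is out of scope;
  alignment-record filtering stands in for it.
* CRAM is accepted only insofar as the runtime's decoder resolves its
  reference; tests pin the SAM dialect.
* The interactive viewer, web API and workflow orchestration that would
  surround a production deployment are deliberately out of scope; the
  package computes the data those layers display.
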