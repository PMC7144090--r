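# blobr

Taxon-annotated GC–coverage datasets for genome assembly quality assessment.

Draft genome assemblies are frequently mixtures: alongside the target genome
they carry contaminants introduced during sample handling and genuine
cobionts (symbionts, parasites, gut flora). `blobr` is an R toolkit for
detecting and separating such non-target sequence. It builds a per-contig
dataset from an assembly and its analysis files, assigns each contig a
putative taxon, and computes the statistics behind the standard QC
visualisations — taxon-annotated GC–coverage ("blob") plots, kite summaries,
cumulative span curves, snail plots and filter-aware BUSCO summaries — with
every filter encodable as a reproducible query string.

It is aimed at genome-assembly groups screening their own drafts before
submission, and at anyone auditing published assemblies for contamination.

## What it computes

**The BlobDir dataset.** A directory of JSON documents, one per per-contig
attribute plus one collated metadata document, with attributes typed as
generic datatypes (identifiers, variables, categories, arrays, arrays of
arrays). A dynamic validator checks datatypes, file presence, value-array
lengths, category indices and metadata ranges against the stored values.

**Per-contig inputs.** From a FASTA assembly: length, GC proportion
(`(G+C)/(A+C+G+T)` over unambiguous bases) and N proportion. From SAM/BAM
alignments: read coverage (count of primary mapped alignments) and base
coverage (aligned M/=/X bases divided by contig length). From BUSCO full
tables: per-contig ortholog annotations with filter-aware recounting.

**Bitscore-sum taxonomy (taxrules).** Given tabular BLAST/Diamond-style hits
with taxids and an NCBI-style taxdump, each contig *c* is assigned, at each
of eight ranks *r* (superkingdom … species), the taxon with the largest
summed bitscore

    score_r(c, t) = Σ { bitscore(h) : h ∈ hits(c), taxon_r(h) = t }

together with that score and a c-index (the number of alternate
positively-scoring taxa at the rank). `bestsum` pools hits across all
databases; `bestsumorder` uses, per contig, only the first database in
priority order that produced a hit. Contigs without hits are `no-hit`.
Helpers cover the surrounding pipeline conventions: splitting contigs longer
than 100 kb into up to 10 near-equal chunks before search (and merging the
chunk hits back), extracting no-hit contigs for a second-pass protein
search, and the read-subsampling proportion for a target maximum coverage.

**View statistics.** Square- (or hex-) binned blob grids at a configurable
resolution (default 30 divisions per axis, sides scaled by the square root
of the binned span), length-weighted kite statistics (weighted mean, ±2 SD
extents, weighted median, weighted least-squares regression, all in
transformed plot coordinates), cumulative span curves by taxon, snail-plot
statistics (N50/N90, GC/AT/N composition, 1000-segment length and GC rings)
and deterministic SVG renderings of each.

**Synthetic data.** A seeded generator produces mixed host/contaminant
assemblies with planted truth — FASTA, SAM, hit tables and a miniature
taxdump — so the whole toolkit builds and tests without any download, plus a
corruptor that injects single violations for validator tests.

## Worked example

Simulate a host (GC 0.35, 30× coverage) plus a proteobacterial contaminant
(GC 0.55, 5×), build the dataset, and pull the contaminant out with a
category filter:

```r
library(blobr)

sim <- cmd_simulate("sim", seed = 42)        # fasta + sam + hits + taxdump
ds <- cmd_create(list(fasta = sim$fasta,
                      alignments = list(lib1 = sim$sam),
                      hits = list(sim$hits), taxdump = sim$taxdump,
                      taxrule = "bestsum", out = "sim/bd"))
summary(ds)
#> BlobDir dataset 'dataset'
#>   records: 85
#>   span: 137,675  N50: 1,827
#>   fields: identifiers, length, gc, n, lib1_cov, lib1_read_cov, bestsum_superkingdom, ...

snail_stats(ds)
#> assembly: span 137,675 count 85
#> longest 3638  N50 1827  N90 1058
#> GC 0.4114  AT 0.5886  N 0.0000

ids <- cmd_filter("sim/bd", query = "bestsum_phylum--Keys=in:Proteobacteria")
length(ids)
#> [1] 25
```

All 25 contaminant contigs (and no host contigs) are retained; the exported
list document reports their span (44,161 bases) and N50 (1,924 bases), and
the same `bestsum_phylum--Keys=in:Proteobacteria` query string reproduces
the selection anywhere — in `cmd_filter`, `cmd_stats`, `cmd_plot` or
`build_mask()`. `render_svg(bin_blob(ds))` draws the binned blob plot the
filter was read off.

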