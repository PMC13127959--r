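---
title: "Reference-guided transcriptome annotation refinement with txrefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided transcriptome annotation refinement with txrefine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txrefine)
```

## The problem

Draft genome annotations are typically built from a narrow range of tissues.
When a deeply sequenced, highly specialized tissue is aligned back to such a
genome, the assembled transcripts routinely reveal three kinds of missing
structure: additional isoforms of annotated genes, evidence that neighboring
annotated "genes" are really parts of one transcription unit, and wholly
novel loci (many of them non-coding). txrefine takes a reference annotation
(GTF), a set of assembled candidate transcripts (StringTie-style GTF with
coverage attributes), a per-transcript expression matrix (RSEM-style
expected counts), and a splice-junction evidence table, and produces an
updated annotation plus the accounting reports a study would publish.

The stages, each exposed as a function over tibbles:

1. **Junction/coverage filter** (`filter_by_junctions()`). A candidate is
   kept only if every splice junction of its intron chain that is *not*
   already in the reference has at least `min_junction_reads` supporting
   spliced reads with at least `min_anchor` aligned bases on each side, and
   (when the assembler reported one) transcript coverage is at least
   `min_coverage`. Defaults are 4 reads, 15 anchor bases, coverage 10 —
   standard assembly-stage thresholds. A junction with no evidence row
   counts as zero reads, not as an error.
2. **Classification** (`classify_transcripts()`). Each candidate is placed
   in a four-way partition by same-strand *exonic* overlap with reference
   genes: 0 genes → `novel_gene`; ≥ 2 genes → `join_evidence`; exactly one
   gene → `exact_match` if some isoform of that gene has an identical intron
   chain (single-exon case: reciprocal overlap ≥ 80%), otherwise
   `novel_isoform`.
3. **Gene merging** (`build_merge_components()`). Join-evidence transcripts
   define edges between the genes they span; connected components of that
   graph are the transcription units to fuse. Connected components, not
   pairwise merges, because chained evidence can link more genes than any
   single transcript spans.
4. **Expression filter** (`expression_filter()`). A novel transcript is
   eliminated if it is expressed in fewer than 30% of samples, or has fewer
   than 10 summed reads over all samples, or carries less than 10% of its
   gene's summed reads.
5. **Integration** (`integrate_annotation()`). Exact matches are dropped;
   novel isoforms attach to their host gene, which keeps its identifier and
   attributes; each merge component becomes one gene under a fresh serial
   identifier (default `GBIG_G_` + 6-digit zero-padded serial) with its
   member genes recorded in a `merged_from` attribute and member transcripts
   keeping their original identifiers; novel transcripts are grouped into
   genes and named `<gene_id>.t<n>`.
6. **Reporting** (`assembly_summary()`, `merge_distribution()`,
   `busco_gene_reconcile()`, `softmask_fractions()`).

`run_pipeline()` chains all of this and writes the artifact set.

## A worked example

```{r example}
fx <- generate_fixture(fixture_config(seed = 7))
res <- run_pipeline(fx$reference, fx$candidates, fx$expression, fx$junctions)
res$log
glance(res$integration)
res$summary
```

Every number above is recomputed from the seeded synthetic study each time
the vignette runs; the classification, merge, and filter outcomes equal the
generator's planted truth (the test suite asserts this exactly).

## Design decisions

**Coordinates and formats.** Coordinates are stored in GTF convention
(1-based, closed) end to end; both `key "value";` and `key=value` attribute
syntax are accepted on read and GTF2.2 is emitted on write, with `gene_id`
and `transcript_id` first and records in a deterministic order (seqid, then
start, then identifier) so repeated writes are byte-identical. Features
other than gene/transcript/exon (CDS, UTR, ...) are carried through
verbatim, attached to their transcript, and never interpreted. Transcript
length always means spliced length (the sum of exon lengths), since that is
what transcriptome FASTA statistics describe.

**Exon-level, stranded overlap.** Classification uses exonic overlap, never
span overlap: a candidate lying wholly inside an intron has zero exonic
overlap and is a novel gene. This matters because intronic non-coding
transcripts are a real and retained class; span overlap would silently
absorb them into the host gene. Antisense-only overlap likewise never links
a candidate to a gene — standard comparison tools treat antisense overlap
as non-matching. One base of same-strand exonic overlap suffices to link a
candidate to a gene for join evidence; upstream junction and expression
filters are the noise guards. Unstranded (`.`) candidates — typically
unspliced single-exon models — match genes on either strand; when that
yields genes on both strands, the gene with the largest exonic overlap wins,
ties broken by smaller gene start, so results are deterministic.

**Structural identity.** Two multi-exon transcripts are structurally
identical iff their intron chains are identical; terminal-exon extents are
free. Single-exon transcripts have empty chains, so identity there needs an
overlap criterion: reciprocal exonic overlap of at least
`min_reciprocal_overlap` (default 0.8), a tool parameter.

**Boundary semantics of the expression filter.** The three rules are
strict-less-than *failure* conditions: a transcript with exactly 10 summed
reads, or expressed in exactly 30% of samples, or carrying exactly 10% of
its gene, passes. "Expressed" means expected count strictly greater than
zero (expected counts are fractional, and no normalized-abundance cutoff is
imposed). The gene denominator uses post-integration membership — merged
units pool all member transcripts, a novel gene's denominator is its own
transcripts — and totals are summed over all samples jointly. A gene total
of zero gives a gene fraction of 1 by convention, so an otherwise dead locus
cannot fail the share rule. The sample fraction is applied as a real-valued
fraction of the sample count, not a rounded integer.

**Merging and identifiers.** Merge components impose no adjacency
constraint: a spanning transcript may skip over an intervening gene, and
"neighboring" is an empirical observation, not a rule. Components require a
shared scaffold implicitly (overlap forces it) and record strand, but
mixed-strand components arising from unstranded evidence are not forbidden.
New identifiers are assigned merge components first, then novel genes, both
in genome-wide genomic order (seqid lexicographic, then leftmost start) —
the identifier format is fixed but the assignment order is this package's
reproducibility convention, as is the `<gene_id>.t<n>` naming of novel
transcripts. Integration refuses a novel isoform whose host gene was
consumed by a merge component the isoform is not part of: that indicates an
inconsistent classification batch, and failing loudly beats guessing.

**Pipeline ordering.** `run_pipeline()` rebuilds merge components from the
join transcripts that *survive* the expression filter, so every merge in
the final annotation is backed by retained evidence; a component whose only
evidence was expression-filtered does not fuse genes. The intermediate
(pre-expression-filter) annotation can be written with
`emit_intermediate = TRUE` for two-pass workflows that re-quantify against
it.

**Rounding.** Reported statistics round half-up at fixed precisions (1
decimal for transcripts-per-gene, 2 decimals for percentages, integer for
mean/median lengths); R's banker's rounding is deliberately not used. The
median of an even count is the half-up-rounded mean of the central pair.

**Gene-level BUSCO reconciliation.** Transcript-level ortholog hits are
collapsed to genes: multiple complete hits on isoforms of one gene are one
single-copy gene, complete hits on two or more genes are a duplication, an
ortholog with only fragmented hits is fragmented, and unobserved orthologs
are missing. Complete takes precedence over fragmented within an ortholog —
the standard precedence. Hit parsing is limited to a minimal three-column
table; adapting a full BUSCO `full_table` is upstream glue, not core logic.

## What the synthetic generator does and does not emulate

`generate_fixture()` builds a seeded toy study: multi-isoform genes placed
without inter-gene exonic overlap on a few scaffolds, same-strand runs of
2–7 neighboring genes for join evidence (cardinality weights follow the
observed merge distribution, where pairwise joins dominate), soft-masked
repeat stretches, 21 expression samples, and candidates planted per
category — exact copies, exon-skip isoform variants, run-spanning
transcripts, intergenic novels, and antisense copies (labelled `novel_gene`
in truth, tagged `antisense` for audit). Expression rows are built from
small integers so the strict-inequality boundaries are exact, and each
planted violation breaks exactly one rule: gene-share violations are
planted on isoform candidates (the only place the denominator is
controllable by construction), and the host genes of total-read and
gene-share plants carry a single reference isoform with fixed totals.

What it does *not* emulate: read-level noise (no FASTQ/BAM — evidence
tables are generated directly), overlapping reference genes, fuzzy exon
boundaries, fractional expected counts from multi-mapping, or assembly
artifacts. Passing tests therefore demonstrate the algebra of the pipeline
— classification, graph closure, filter boundaries, identifier conservation
— on clean structure, not robustness to misassembly; on real data the
junction and expression thresholds carry that burden.

## Problem sizes and numerical notes

The test suite runs the classifier against an independent quadratic
exon-pair oracle on 500 seeded candidates over 600 genes, the merge builder
against a breadth-first-search oracle on 1,000 random join sets over 700
genes, and the expression filter against per-rule recomputation on 220
planted transcripts; the end-to-end fixtures use 60–120 genes. These sizes
were chosen so every oracle remains brute-force-simple while each check
still exercises hundreds of independent random cases. Half-up rounding adds
a 10⁻⁹ guard before truncation so values such as 2.05 stored just below
their decimal representation still round up. Degenerate inputs are defined,
not special-cased: an empty annotation summarises to zeros, an empty
candidate set leaves the reference unchanged byte-for-byte, and a
zero-expression gene yields fraction 1 as above.

## Limitations

Only merges are modelled — there is no gene *splitting* (the inverse
operation), no ORF or coding-potential prediction, no normalization or
re-quantification, and no full reproduction of the many-class comparison
taxonomies of tools like GFFcompare beyond the four-way partition the
integrator needs. tRNA and other pass-through gene records are carried as
ordinary genes. Evidence extraction from alignments (BAM parsing) is
upstream of this tool.
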