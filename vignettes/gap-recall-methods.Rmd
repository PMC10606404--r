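---
title: "Recovering lost contigs in chromosome-level assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering lost contigs in chromosome-level assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Scaffolding a contig-level assembly into chromosomes discards contigs it
cannot place. The discarded sequence is not unassembled — it exists in the
contig sets of one or more assemblers — it is merely *lost* from the
chromosome-level product. `contigrecall` treats single-copy marker genes
(near-universal orthologs expected exactly once per haploid genome) as
sentinels for such losses: a marker that is Missing from the chromosomes
but full-length in a merged multi-assembler contig set pinpoints a lost
region, and the surrounding contig tells us what sequence belongs there.

The pipeline is a chain of four pure transformations:

1. **Prepare.** Completeness scans of the chromosome assembly and of the
   merged contig set, each yielding a per-gene status table
   (Complete/Duplicated/Fragmented/Missing with locations). The fillable
   set is `Missing(chromosomes) ∩ full-length(contigs)`.
2. **Locate.** The *whole* host contig of a fillable gene is the missing
   genomic region — deliberately broader than the gene itself, so that
   read recall captures the entire lost segment and its junctions. The
   contig is anchored to a chromosome interval by its best whole-genome
   alignment.
3. **Recall.** Reads aligned to the contig are unioned with reads aligned
   to the anchor's neighborhood (anchor interval ± `flank_bp`), locally
   reassembled, and the candidate on which the target gene scans Complete
   is selected (longest first).
4. **Replace.** The candidate is aligned back to the chromosomes; the
   splice happens only if the alignment covers most of the candidate and
   the gene interval lies fully inside the aligned query span. The
   alignment's target interval is replaced by the candidate's aligned
   bases (reverse-complemented for minus-strand alignments). A final
   re-scan verifies no gene's status worsened and the Missing count did
   not grow; otherwise the output is withheld.

All internal coordinates, everywhere, are 0-based half-open; conversion to
1-based inclusive happens only at the BUSCO-table serialization boundary,
and PAF is already native 0-based half-open.

## Design choices made where the design was open

**Duplicated contig hits are eligible.** Merging the contig sets of
several assemblers means every recoverable region typically appears once
per assembler, so its gene scans as Duplicated — never Complete — in the
merged set. Restricting eligibility to Complete would therefore empty the
fillable list in exactly the intended use case. We accept Complete and
Duplicated (any full-length copy carries the gene) and resolve Duplicated
hits deterministically: highest score, then lexicographically smaller
contig id, then smaller start. Fragmented hits stay ineligible: no single
contig carries the whole gene, so nothing can be validated after splicing.

**Anchor choice is an argmax.** How the original method filters
contig-to-chromosome alignments is unspecified; we take, among primary
alignments (`tp:A:P` when the aligner emits the flag), the record
maximizing residue matches, with ties broken by larger block length, then
target id, then target start, subject to a floor of
`min_anchor_matches = 500` matching bases. The floor exists to stop a
short repeat match from anchoring a contig to the wrong chromosome;
contigs failing it are processed unanchored (contig-only recall,
genome-wide candidate alignment).

**Neighborhood flank.** "Neighboring genomic region" is quantified as
`flank_bp = 50000` (50 kb) on each side of the anchor: comfortably larger
than a read length, so every junction-spanning read is recalled, while
staying local. Recall is provably monotone in the flank (a larger flank
never recalls fewer reads), which the test suite checks.

**Replacement span = the alignment's target interval,** not the whole
anchor: the local alignment defines which chromosome bases correspond to
the candidate; replacing more would risk deleting correct flanking
sequence. `min_query_coverage = 0.8` guards against splicing a candidate
that aligns only by one repeat arm.

**Processing order and conflicts.** Genes are processed in ascending
(chromosome id, anchor start) order, unanchored genes last, ties by gene
id. When two applied events overlap on a chromosome, the later one (in
this order) is demoted to `skipped_overlap` rather than aborting the run —
gene-by-gene partial success is the method's accounting model. A demoted
gene is frequently still recovered, because the earlier, overlapping
splice restored its locus too; recovery is therefore always counted from
the before/after status tables, not from event statuses.

**Candidate integrity is judged per candidate.** A gene present on two
assembled candidates is Complete on each of them; pooling the candidates
into one scan would misclassify it as Duplicated and reject both.

## The built-in toy components

These are deterministic, exactness-based stand-ins valid in the low-error
regime of the fixtures (and of HiFi-like reads at desk scale). External
tools replace them on real data via command-template adapters.

**Marker scanner.** A marker is Complete when its exact sequence occurs
exactly once in the assembly (either strand), Duplicated when more often,
Fragmented when some contiguous window of at least `min_fragment_fraction`
(default 0.5) of its length occurs (found by a constant-width dictionary
search over all marker windows), else Missing.

**Aligner.** Exact k-mers (`k = 31`) sampled every `stride = 20` bases of
the query (plus the final position) are looked up in a full k-mer index of
the target, grouped into same-diagonal runs, and chained colinearly with
gaps up to `max_gap = 20000` bp — large enough to bridge an excised locus
(5 kb at the default fixture geometry), small enough not to chain across
unrelated loci. Chains with query span ≥ `min_chain_bp = 500` become PAF
records; `residue_matches` is the chained anchor coverage, which equals
the full match length for exact containments because the stride does not
exceed k. The best record per query is flagged primary. Repetitive k-mers
are matched at all their target positions; chaining picks the colinear
subset.

**Assembler.** Greedy overlap-layout on exact reads: contained reads are
retired, then contigs grow seed-and-extend (seeds longest-first, ties by
id), merging at each step the read with the longest exact suffix–prefix
overlap ≥ `min_olap = 500` bp, both ends and both strands considered, and
retiring reads that become contained in the growing contig. Everything is
deterministic; on error-free reads fully tiling a non-repetitive segment
it reconstructs a sequence containing that segment exactly, which is the
property the pipeline needs and the tests assert.

## The synthetic fixture generator

The generator emulates the structure of the method's validation data with
full provenance: a uniform-random truth genome (default 2 chromosomes ×
100 kb) carrying `n_markers = 6` random unique 1 kb markers planted at
non-overlapping loci (uniform spaced placement, each verified unique
genome-wide); a degraded chromosome assembly with each dropped gene's
locus ± `contig_margin_bp = 2000` excised (or N-filled); two
boundary-jittered lost-contig sets that extend a further margin beyond the
removed segment, so each contig shares flanks with the remaining
chromosome — which is what makes anchoring possible, exactly as a real
lost contig overlaps its scaffold neighborhood; and simulated reads:
uniform positions, random strand, normal lengths (mean 15 kb, sd 1.5 kb,
clamped ≥ 1 kb), depth 20, substitution errors at `error_rate` (default 0,
approximating HiFi accuracy at this scale).

Diploid mode derives a second haplotype by an independent per-base
mutation scan — substitution 0.02, insertion 0.02, deletion 0.02 per base,
indel length 12 bp — and draws half the depth from each haplotype. Bases
inside a deletion are skipped by the scan, so deletions never overlap; the
expected output length is `L(1 + 12·ins)/(1 + 12·del)`, i.e. first-order
`L(1 + 12(ins − del))` and exactly `L` at balanced rates. Realized event
counts are returned so statistical tests can condition on them.

What the generator does *not* emulate: repeat landscapes, centromeres and
telomeres, GC/composition bias, quality scores, multi-pass consensus read
error profiles, or real chimeric/misassembled contigs. Passing tests on
these fixtures demonstrate the correctness of the bookkeeping — set
difference, anchoring, recall, assembly, splicing, offsets, regression
checking — not the sensitivity of external aligners/assessors on noisy
real data.

## Numerical and degenerate-input conventions

* All generators take an integer seed and restore the caller's RNG state;
  identical seeds give byte-identical output.
* Every selection (anchor, candidate, merge partner, event order) has a
  total, documented tie-break, so the whole pipeline is a pure function of
  its inputs.
* Zero fillable genes short-circuits to a byte-identical pass-through;
  an empty recall set skips the region; a failed candidate selection is a
  per-gene skip, never an error.
* PAF rows violating coordinate invariants are dropped with a warning
  naming line numbers; structurally malformed rows (missing columns,
  non-integer coordinates) abort. A gene listed Complete on several rows
  of a status table is reclassified Duplicated at construction.
* Splice events out of chromosome bounds abort; overlap conflicts demote.

## Problem sizes used by the test suite

Unit tests run on a reduced fixture (2 × 40 kb chromosomes, four 500 bp
markers, two dropped, depth 12, 4 kb reads); the end-to-end property tests
and the acceptance script use the full study conditions (2 × 100 kb, six
1 kb markers, three dropped with 2 kb margins, depth 20, 15 kb reads,
diploid divergence 2%/2%/2% with 12 bp indels). These sizes keep every
suite deterministic and fast while leaving all rates and geometries at
their defaults.

## Known limitations

* Regions lacking single-copy markers are invisible to the method by
  construction.
* A gene lying outside its candidate's aligned span is skipped, not
  forced in; this is the method's own named failure mode and is surfaced
  as `skipped_gene_outside_alignment`.
* The toy aligner/assembler assume near-exact sequence; at high divergence
  (e.g. the 2%-SNP second haplotype) they still behave correctly — same-
  haplotype reads assemble together and cross-haplotype exact merges are
  vanishingly unlikely — but sensitivity on genuinely noisy data is the
  job of the external adapters.
* Chimeric (split-aligning) contigs get a single best anchor; Hi-C or
  map-based anchoring is out of scope.
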