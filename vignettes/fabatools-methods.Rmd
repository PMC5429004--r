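---
title: "Methods: coverage classification, splice detection, organelle variants and homology maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage classification, splice detection, organelle variants and homology maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabatools)
```

# Scope and model of the data

`fabatools` implements the downstream analyses used to build genome
resources for faba bean (*Vicia faba*), a diploid legume with a ~13 Gb
nuclear genome dominated by repeats. Short-read data for such a genome
cannot support a contiguous assembly, so the informative analyses are
indirect: partitioning reads among genomic compartments, verifying
transcriptome unigene models by coverage structure, locating introns by
softclip clustering, extending linkage-marker loci with de novo contigs,
and characterizing the much smaller organelle genomes (SNVs and
inter-species homology). Each stage is a small, exactly specified
computation over standard formats (FASTA, SAM/BAM, GFF3, VCF, TSV); this
vignette records the models, parameter choices and numerical conventions.

All internal coordinates are 0-based half-open; SAM, GFF3 and VCF
coordinates are converted only at the file boundary. Reported SNV
positions are 1-based, matching VCF and printed variant tables.

# The synthetic-data generator

Every pipeline input can be generated with known truth
(`simulate_transcriptome()`, `simulate_genomic_alignments()`,
`simulate_organelle()`, `simulate_markers_and_contigs()`,
`simulate_repeat_assignments()`), so each stage is testable without any
download. Design choices:

* **SAM is emitted directly from truth geometry** — no aligner runs. A
  genomic read that spans a planted exon-exon junction is emitted as two
  softclip-bearing records (the upstream fragment ends at the junction
  with a trailing clip; the downstream fragment starts there with a
  leading clip, clipped bases drawn from random "intron" sequence). This
  guarantees the clip geometry the detector is specified against and
  keeps coverage conserved across the junction.
* **Defaults are the study conditions**: 100 bp reads; unigenes of
  300-3000 bp with uniform-random sequence; per-unigene coverage classes
  drawn from the bin structure of the verification table with full-length
  mean-depth targets {5, 30, 150} for the three depth bins and covered
  fractions {0.98, 0.70, 0.30} for the three breadth bins; a 130 kb
  plastome-like organelle with ~40 CDS plus tRNA/rRNA features; organelle
  SNVs at allele fraction 1.0 (near-homoplasmic); constant base quality
  Q40; sequencing-error rate 0 by default (an optional uniform
  substitution rate exercises caller thresholds).
* **Determinism**: a fixed master seed makes every output byte-identical;
  each generator derives an independent stream from it, and
  `with_seed()` restores the caller's RNG state.
* What the simulator does **not** emulate: realistic Illumina error and
  quality profiles, PCR duplicates, paired-end insert-size structure
  (records are single-end-style, since no downstream stage consumes mate
  information), structural variants, and reads crossing the circular
  origin of the organelle. Passing tests therefore demonstrate
  correctness of the computations under clean, well-posed inputs, not
  robustness to real-library artefacts.

Truth SNV effects are computed by brute-force translation of the whole
mutated CDS (`effect_by_translation()`), a deliberately independent route
from the codon-level annotation in `annotate_effects()`; the test suite
asserts their equivalence.

# Read accounting

`account_compartments()` partitions total read pairs among disjoint
compartments; when a read could match several references the upstream
assignment priority is chloroplast > mitochondrion > transcriptome >
repeat database > unaligned (organelle-first matches the way organelle
coverage is interpreted; counts are consumed as already-disjoint).
Percentages are rounded half away from zero — `round_half_up()` — at two
decimals for compartments and six decimals for repeat classes, the
precisions such tables print; the repeat-total row uses two decimals.
Depth is reported as aligned bases / reference length
(`estimate_depth()`); no attempt is made to reproduce any particular
published depth convention, which cannot be reconstructed from pair
counts and reference lengths alone.

The package ships the published faba bean compartment and repeat-class
paired-read counts (`faba_read_counts()`) as worked inputs; the four
compartment counts sum exactly to the printed total of 812,092,660 pairs,
and the 29 repeat-class counts sum to the printed repeat total.

# Unigene verification

A *peak* is a maximal run of positions with depth ≥ `min_depth`
(default 1); runs separated by ≤ `max_gap` uncovered positions merge.
`max_gap = 0` by default: peaks stand for independent read clusters, so
strict contiguity is the natural reading. *Breadth* is the percentage of
positions covered at depth ≥ 1. *Mean depth* is averaged over the full
unigene length, not only covered positions — the stricter reading of
"average coverage per base", and the one that makes the depth bins
monotone in total aligned bases.

Bin boundaries partition all values: breadth >95 / [50, 95] / <50 (the
boundary values 95 and 50 fall in the middle bin, avoiding gaps between
printed open-looking bins), depth <10 / [10, 100] / >100, peak count
0 / 1 / 2-3 / 4-10 / >10. The `0` peak bin is exposed for zero-breadth
unigenes. `tabulate_classes()` crosses the three factors; cells always
sum to the number of unigenes.

# Splice-point detection

Unspliced genomic reads aligned to a spliced transcript cannot extend
past an exon-exon junction; aligners emit the unalignable tail as a
softclip, so clip boundaries pile up at the junction.
`collect_clip_boundaries()` maps a leading clip to the alignment start
and a trailing clip to the alignment end; both ends of a doubly-clipped
record count. Clips shorter than 5 bp are ignored as alignment noise
(adapter stubs and terminal mismatches produce such micro-clips on real
data).

`call_splice_points()` slides a 2 bp window (the published clustering
width) over the boundary counts. A window qualifies when summed support
reaches `min_support` (default 5 — a cluster, not a singleton; no
support threshold is published, so it is exposed as a parameter) and
also `min_fraction` (default 0.1) of the local total, taken as depth at
the modal boundary plus the clip count, since clipped fragments need not
contribute depth at the boundary itself. Overlapping qualifying windows
are merged greedily, highest support first with ties to the leftmost
position — the merging rule is a package decision; nothing is published
about adjacent windows — and each call is placed at the modal boundary.
Consequently no two calls lie within the window size of each other, and
on clean simulated data recall and precision against planted junctions
are both 1.0 with every call within ±1 bp.

# Marker matching and contig extension

`match_contigs()` searches both strands of each contig (≥ 1 kb after the
usual pre-filter) against full-length linkage-marker sequences with local
alignment (match +1, mismatch −2, gap open 5, gap extend 2) and keeps the
best match per contig by identity × coverage. Identity is matches /
alignment columns, gaps counting as mismatches. Coverage is measured over
the *alignable* portion of the contig: contig bases whose projection
falls beyond a marker end are excluded from the denominator. This is the
package's reading of the "95% of a contig" criterion, and it is the only
reading under which a contig can both satisfy the criterion and extend a
marker by more than 5% of its own length — extensions of up to ~3 kb
against ≤ 5 kb sequences are expected in this analysis, and a coverage
denominator that includes the overhang would make them impossible by
construction.

`extend_marker()` appends overhanging contig sequence (already in marker
orientation) to the marker ends; a contig internal to the marker span
confirms it with 0 bp added. When several passing contigs would extend
one marker, `extend_markers()` applies overhangs greedily longest-first,
one per marker end, and reports later conflicting contigs as filtered —
whether published analyses merged several contigs per marker is unstated,
so best-only is the default and multi-contig application is conservative.
The merged sequence always contains the marker verbatim.

# Organelle variants

`build_pileup()` delegates the mpileup-style tally to `Rsamtools::pileup`
with a base-quality floor of Q13 (the classic mpileup default; the Q30
threshold used in read trimming belongs to an upstream stage that is out
of scope here), primary alignments only, and deletion-spanning reads
counted in depth but contributing no base. `call_snvs()` emits a call
where the most frequent non-reference base has fraction ≥ 0.8 at depth
≥ 10 — organelles are near-homoplasmic, so real variants sit near
fraction 1 and the threshold mainly rejects alignment noise; one alt per
site, ties broken alphabetically.

`annotate_effects()` locates the containing feature, splices the CDS,
reverse-complements minus-strand genes, and translates the reference and
alternate codons under the standard genetic code (table 1) with no
initiator-codon special-casing, so a start codon mutated away from ATG
classifies like any other codon change. tRNA/rRNA hits are
`NON_CODING_GENE` (rendered as a dash), positions outside any feature
`NONCODING`; stop gains render as `X->STOP`. Plant-mitochondrial C-to-U
RNA editing is *not* modeled; where editing restores or creates codons,
effect calls based on genomic sequence can differ from the biological
consequence — a documented limitation. Indels are out of scope;
substitutions only. A CDS whose spliced length is not divisible by 3 is
a fatal annotation error rather than a silent frameshift guess.

# Homology maps

`align_gene_pair()` is a deterministic global alignment (match +1,
mismatch −1, gap open 4, gap extend 1, end gaps penalized) built on
`Biostrings::pairwiseAlignment`. Global rather than local: regions absent
from one species' coding sequence must appear as gap columns (they render
as absent frames), not be clipped away as a local aligner would. The
exhaustive dynamic-programming oracle in the test suite checks the
*optimal score*; traceback tie-breaking among co-optimal alignments is
the library's and is not asserted.

`frame_identity()` tiles the *alignment* (including gap columns) with
non-overlapping 10 bp frames — the maps are drawn over a common axis, so
frames must tile the alignment, not either raw sequence. Per frame,
identity is 100 × matching columns / frame width (one mismatch in a full
frame gives 90%); the last frame may be short and is scored over its
actual width. Frames consisting entirely of gap-versus-base columns are
flagged absent and score 0, and the per-gene mean includes them, so a
deletion shows up as lost homology rather than being silently skipped.
Comparison is at the nucleotide level (CDS DNA), not protein.

Gene names are canonicalized by case-folding plus an editable synonym
table (`inst/extdata/gene_synonyms.tsv`, covering locus-tag variants such
as `rrn26.r01`); unresolved names pass through. `core_gene_set()`
intersects canonical names across species; `multiway_summary()` averages
pairwise mean identities over all n(n−1)/2 species pairs (55 pairs for 11
species, 15 for 6).

# Problem sizes and determinism of the shipped analyses

The numbered scripts under `analysis/` and the acceptance checks run the
pipeline at desk scale: 50-200 unigenes, a 60-130 kb organelle at depth
30-50, five marker/contig pairs, and 10-gene/11-species homology sets.
These sizes exercise every code path (all class bins populated, all
effect categories reachable, absent frames present) while keeping each
script in the seconds-to-a-minute range. Published headline counts from
the ~812 M-read dataset (e.g. tens of thousands of verified unigenes and
splice points) depend on that data volume and are not reproducible at
this scale; what is checked instead is exact recovery of planted truth
and exact reproduction of the printed table arithmetic.

# Known limitations

* Clean-read simulation: thresholds are exercised by an optional uniform
  error model, but no empirical error/quality profile is available.
* Organelle circularity is annotational; simulated reads do not cross
  the origin, and features are placed away from it.
* The SNV caller targets near-fixed substitutions; heteroplasmy
  quantification and indels are out of scope.
* Repeat-database search itself (read-vs-library alignment) is upstream;
  the package consumes per-read best-hit class assignments.
* Mean depth over the full unigene length makes the depth bin of very
  low-breadth unigenes conservative by design.
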