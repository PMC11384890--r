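---
title: "Homopolymer-aware mitogenome annotation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homopolymer-aware mitogenome annotation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyanno)
```

## The problem

The mitochondrial genome of the appendicularian tunicate *Oikopleura
dioica* is dominated by homopolymers: on the deposited strand, adenine and
thymine runs of six bases or more cumulatively cover close to half of the
~39 kb molecule, most of it in a large noncoding control region.
Protein-coding genes carry long poly-T insertions that are absent from the
mature mRNAs: a post-transcriptional editing mechanism collapses every
genomic T-tract longer than six down to exactly six T's in the transcript,
removing isolated non-T bases embedded in the tract along with it.
Conventional mitogenome annotators assume transcripts are colinear with the
genome and fail on such sequences.

The genome's own organization, however, makes it annotatable from first
principles:

* every coding gene ends with a TAA stop immediately followed by a
  genomically encoded poly-A spacer longer than six bases — genes are
  *separated by* poly-A, not edited out of it;
* no A-homopolymer of six or more bases occurs inside an open reading
  frame on the coding strand;
* every T-homopolymer longer than six inside a gene is an edited site, and
  its transcript image is exactly six T's.

`polyanno` turns this grammar into a pipeline: homopolymer profiling, an
explicit editing model with a genome/transcript coordinate map, edit-aware
local alignment, ORF calling under the ascidian mitochondrial genetic code
(NCBI translation table 13: TGA→Trp, AGA/AGG→Gly, ATA→Met, stops TAA/TAG,
starts TTG/ATA/ATG/GTG), structural validation, and a simulator that
generates genomes obeying the same grammar with full ground truth.

## The editing model

`find_editable_tracts()` scans a coding-strand sequence for *chains*:
maximal groups of T-runs in which consecutive runs may be bridged across
single non-T bases, each interruption flanked by at least one T on both
sides.  A chain is *editable* when its total T-count exceeds the collapse
threshold (default 6, the value observed in *O. dioica*) **and** it carries
at most `max_interruptions` interruptions (default 2; the evidence says
only that "a few" non-T bases occur per tract, so the cap is configurable).

Two design points deserve justification:

* **Chains are maximal and never split.**  A chain with too many
  interruptions is left whole rather than carved into editable sub-tracts.
  Splitting would leave two collapsed 6-T remnants bridged by a single
  base — itself an editable configuration — so editing would not be
  idempotent.  With maximal chains, `edit_dna_to_rna()` provably satisfies
  `edit(edit(x)) == edit(x)`, which the test suite checks on hundreds of
  random AT-rich strings.
* **The retained six T's are taken from the 5′ end of the tract.**  Any
  placement is biologically equivalent; a fixed convention makes outputs
  reproducible and coordinate maps well defined.

`edit_dna_to_rna()` returns, besides the edited string and the event
table, a bidirectional coordinate map (`rna_to_dna`, `dna_to_rna`): every
retained transcript base maps to the genomic base with the same letter, and
deleted genomic bases map to the last retained transcript position before
them.  `count_edited_sites()` applies tract detection to a gene's
coding-strand sequence (reverse-complementing minus-strand genes) and is
the package's equivalent of the per-gene "number of edited homopolymers"
column of an annotation table.  A tract interrupted by a non-T base counts
once; if a curator prefers to count the flanking runs separately, the
event table carries the interruption positions needed to do so.

## Alignment

`smith_waterman()` is a Gotoh affine-gap local aligner (Rcpp, rolling
score rows, one packed traceback byte per cell, so a transcript against a
doubled mitogenome stays in the hundreds of MB).  A gap of length
*L* costs `gap_open + (L-1) * gap_extend`; the default nucleotide scheme is
match 5, mismatch −4, gap −10/−0.5 — the EMBOSS `water` defaults, since the
original analysis used `water` without reporting parameters — and the
protein scheme is BLOSUM62 (from Biostrings) with the same gap penalties.
The traceback is deterministic (best cell = highest score at smallest
coordinates; ties prefer diagonal, then query-consuming, then
target-consuming moves), and the suite cross-checks scores against a
plain-R dynamic program, exhaustive path enumeration on tiny pairs, and
`Biostrings::pairwiseAlignment`.

Circularity is handled by aligning against the doubled genome and
rejecting hits longer than one wrap; coordinates are lifted back modulo the
genome length.  ORF discovery on circles walks the codon cycle directly
(`1, 4, 7, … mod L`), which is exact and rotation-invariant; stop-free
readings around the entire circle have no canonical start and are reported
anchored at their smallest position, capped at one wrap.

Alignment gaps inside homopolymers are placement-degenerate, so
`map_transcript_to_genome()` normalizes every gap to its 5′-most placement
before classification (`left_shift_gaps()`).  Each transcript-side gap is
then classified as `poly_T_edit` (it sits in an editable tract whose
collapse removes exactly the gapped bases), `poly_A_spacer` (an A-run
longer than the threshold — the inter-gene separator), or `other`.  Two
subtleties are handled explicitly:

* a tract whose interruption base equals a flanking base lets the gap
  slide one base outside the tract, so classification requires overlap
  plus an exact removable-base count rather than containment;
* under `water` scoring, a tract that sheds a single base can score 0.5
  better merged into a neighbouring tract's gap plus one mismatch than as
  its own gap (opening costs 10, a mismatch 9).  Within each gene block
  the editing model is therefore used as arbiter: when
  `edit_dna_to_rna(genomic block)` reproduces the transcript block
  exactly, the model's own tract list replaces the alignment's gap calls.
  Blocks the model cannot explain keep their per-gap classification, so
  genuine transcript/genome differences are still visible.

## Annotation

`annotate_genes()` mirrors the published procedure.  Each (polycistronic)
transcript is mapped onto both genome strands; the best alignment's
poly-A spacer gaps cut the transcript into gene blocks — the structural
principle that genes are separated by genomically encoded poly-A.  Within
each block the longest sense-strand start-to-stop ORF (table 13) defines
the coding extent, and its endpoints are projected back to genomic
coordinates through the alignment.  Because gap placement inside the
spacer A-run is degenerate, the projection anchors each gene end on the
stop codon's T — the nearest uniquely aligned base — and adds the two A's
of TAA; gene starts are exact because left-shifted gaps leave the
3′-most bases of a homopolymer aligned.  Reported gene coordinates are
1-based inclusive on the deposited strand and include the stop codon.

Gene symbols come from user-supplied protein queries via
`six_frame_search()` (a tblastn-style protein-vs-genome search over all
six frames) when provided; otherwise genes are numbered in genomic order.
ORFs of at least `orphan_min_aa` amino acids that no transcript or query
covers are reported with the symbol `orfX` — this is how the pipeline
surfaces the unidentified reading frame between *cox1* and *cob* without
claiming an identity for it.  A gene whose 5′ region contains an A-run of
threshold length with an alternative in-frame start downstream is flagged
`ambiguous_start` (the *cob* situation, where available evidence cannot
say whether translation starts before or after the run).

`validate_structure()` re-checks every annotation against the grammar:
TAA stop; following A-run longer than the threshold; no internal A-run of
threshold length or more; edited CDS divisible by 3 with no internal stop.
The CLI exits with status 2 when violations are found so pipelines can
gate on it.

## The simulator and what it does (not) show

`simulation_spec()` defaults describe a genome of the kind the pipeline
targets: 8 genes of 200–680 codons (the span of the published coordinate
table), a quarter of them on the minus strand (2 of 8 in the published
annotation), 3–12 edited sites per gene (the published per-gene range),
poly-A spacers of 7–20 bases, a 22 kb control region of alternating A/T
tracts (6–30 bases, uniform) separated by short C/G spacers, and poly-T
insertions of 7–15 T's with one embedded non-T base at probability 0.2.
The insertion length distribution is **not** reported for the real genome;
7–15 is an arbitrary, documented choice.  Tracts are planted at codon
boundaries with a two-base T-free margin so that the edited image — the
CDS with six retained T's per site, read as two phenylalanine codons —
stays in frame, stop-free, and chain-separate; the margin is what makes
exact ground-truth recovery a well-posed target.

The tests and the acceptance script run the simulator at reduced problem
sizes (3 genes of 40–90 codons, 300 bp control regions, 100 seeds) so the
whole suite completes in minutes; the CLI and the defaults exercise the
full ~35 kb scale.  Synthetic genomes are *cleaner* than the real one: no
sequencing error, no transcript truncation, no ncRNAs, spacer/tract
lengths from simple uniform distributions, and a control region that is
denser in homopolymers than a real one need be.  Passing the recovery
properties therefore demonstrates the pipeline's internal consistency —
planted coordinates, strands and edited-site counts are recovered exactly
— not its robustness to noisy data.  Conversely, the published per-strand
coverage asymmetry (34.8% A vs 13.6% T) is a property of the real control
region that the symmetric simulator does not emulate; reproducing those
numbers requires the deposited sequence itself (see the acceptance tests,
which load it from `inst/extdata/PP146516.fasta` when present).

## Numerical and degenerate-input choices

* Thresholds: runs and editing default to 6, strict inequality for
  editability ("longer than six") and for spacers, at-or-above for the
  run profile ("six or more").
* `N` breaks homopolymer runs and never matches in alignment (a run is a
  run of literal identical bases).
* Percentages are formatted by explicit half-up rounding to one decimal
  (`percent_1dp()`), matching how such coverage figures are usually
  printed; `round()`'s banker's rounding can differ in the last digit.
* A full-circle single-base sequence is one run covering every position
  once; coverage is capped at the sequence length.
* Empty alignments (no positive-scoring cell) return score 0 with empty
  intervals rather than an error; unmappable transcripts yield an explicit
  unmapped result and are listed as skipped by `annotate_genes()`.
* All randomness flows through R's default generator from a single seed
  per simulation, so fixtures are reproducible across platforms.

## Known limitations

* No tRNA/rRNA/ncRNA annotation — none is known for this genome.
* Editing of non-coding transcripts is not modelled; whether the control
  region is transcribed and edited is an open question.
* A-tract editing is deliberately not modelled: poly-A occurs between
  genes, directly encoded in the genome.
* The aligner is the full dynamic program; there is no heuristic seeding,
  so genome-scale protein searches are seconds-to-minutes, not
  milliseconds.
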