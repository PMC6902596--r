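---
title: "Detecting repeat-mediated recombination in circular mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting repeat-mediated recombination in circular mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorecomb)
```

## The problem

Plant mitochondrial genomes assemble as a single circular "master"
molecule, but dispersed repeated sequences can mediate intramolecular
homologous recombination, so that a population of mitochondria in one
plant may carry several genome conformations at once.  Recombination
across a pair of **direct** repeats (same orientation) excises the
inter-copy segment as a subcircle; across an **inverted** pair it
inverts the segment.  In bryophytes — and in liverworts in particular —
such recombination is rare and the gene order is strongly conserved, so
detecting the minority conformations requires counting individual read
pairs that span a recombinant junction.

`mitorecomb` packages that assay end to end: repeat discovery on the
circle, construction of master/alternative junction reference panels,
read-pair classification and rate estimation, prediction of the
recombinant gene orders, genome composition and intron profiling, and a
fully ground-truthed synthetic data generator.

## The recombination assay

For each *assayable* repeat pair (aligned length 50–250 bp, copies
disjoint) a **reference panel** is built.  Each member is

```
up-flank (<= 200 bp) + repeat copy + down-flank (<= 200 bp)
```

read on a single strand (the second copy of an inverted pair is
reverse-complemented together with its flanks).  Two members are the
in-genome *originals*.  When the copies are identical there are two
recombinant junctions — the two flank swaps `up1+R+down2` and
`up2+R+down1` — giving a panel of **4**.  When the copies have diverged,
the repeat sequence itself distinguishes products, and the panel has
**8** members: the four crossover products (both flank swaps × both
copy sequences) plus the two conversion products (each original flank
context carrying the other copy's sequence).  The published procedure
states only that six recombined references are built for diverged
copies without enumerating them; the crossover + conversion set is the
natural six-member set generated by homologous exchange between
non-identical copies and is the one implemented here.

A read pair **supports** a member when both mates align to it
end-to-end (no clipping), inward-facing, each mate at ≥ 98 % identity
over its full length, the implied insert is ≤ 1000 bp, and the pair
footprint reaches at least 50 bp into *both* flanks — i.e. the pair
genuinely anchors both sides of the junction.  A pair whose best
support (fewest total mismatches) is *equal* for an original and a
recombinant member cannot discriminate the conformations and is counted
ambiguous, excluded from both sides; a pair with strictly better
support on one class is assigned to it.  The per-repeat
**recombination rate** is

$$\text{rate} = 100 \cdot \frac{n_\text{alternative}}{n_\text{master} + n_\text{alternative}}$$

reported to two decimals.  The 50–250 bp assayable window follows from
the sequencing design: with 2×150 bp reads and ~350 bp inserts, a pair
can only anchor 50 bp on both sides of repeats up to about 250 bp.  The
upper bound is a parameter (`max_len`), since surveys occasionally
include slightly longer repeats.

Mate placement uses exact-word anchoring with pigeonhole-complete
seeds: a 150 bp mate within the 2 % mismatch allowance (≤ 3
mismatches) always contains a clean 20-mer in one of four evenly spaced
blocks, so anchoring plus full-length byte verification is exactly
equivalent to exhaustive end-to-end placement, at a fraction of the
cost.  A global prefilter (shared 20-mer with any panel member, via a
`Biostrings` PDict) removes the reads that cannot align at all.

## Repeat discovery

Dispersed repeats are found by seed-and-extend on the circular
sequence: exact 11 bp seed words (the classic blastn word size) are
hashed; seed pairs are clustered by diagonal (direct) or anti-diagonal
(inverted, against the reverse complement) and each cluster is extended
**ungapped** under match +1 / mismatch −2 scoring, trimmed to all
maximal scoring segments with the Ruzzo–Tompa algorithm.  Circularity
is handled by working on the tripled sequence and deduplicating
coordinates modulo the genome length; mirror duplicates are collapsed
by canonical copy ordering, and pairs contained in a larger pair are
collapsed to the maximal-scoring one.  Repeats are reported when the
aligned length is ≥ 50 bp and identity ≥ 85 % — the classical
thresholds for potentially recombinogenic organellar repeats — with
identity always recomputable from the stored aligned copies.

The extension is deliberately ungapped.  Organellar repeat divergence
at these identity levels is dominated by substitutions (the synthetic
generator likewise diverges copies by point mutations only), and an
ungapped extension is *exactly* the quantity an exhaustive
all-diagonal enumeration computes, which makes the finder verifiable
against a brute-force oracle with zero tolerance: the test suite checks
equality of the full result set on dozens of seeded genomes.  A repeat
pair containing an indel would surface as two adjacent pairs rather
than one gapped alignment; for the recombination assay this is
inconsequential (each sub-pair is assayed on its own junctions), but it
is a known representational limit.

With 11 bp seeds, a planted repeat of length ≥ 100 bp at identity
≥ 94 % is guaranteed (pigeonhole) to contain a clean seed word, so
detection of such repeats is deterministic, not probabilistic.
Shorter, more diverged repeats near the 50 bp / 85 % floor may lack an
exact 11-mer in adversarial mutation placements; at the identity levels
observed in real surveys (median ≈ 94 %) this is not a practical
concern.

## Structural outcomes and gene orders

`apply_recombination()` rebuilds the recombinant molecules at sequence
level: for an inverted pair, one circle with the inter-copy segment
(the arc from the end of copy 1 to the start of copy 2, in ascending
coordinates — the deterministic convention matching how linearised
assemblies are printed) reverse-complemented; for a direct pair, the
deleted circle plus the excision subcircle.  Features are remapped into
the products; features broken at a junction are dropped with a warning
(they are by construction repeat-overlapping, hence already reported in
`genes_affected`).  The inversion product is rotated back to the master
coordinate frame, which makes recombination across an inverted pair an
involution — a property the tests exercise.

"Gene order changed" is operationalised as a change in the
**canonical signed circular adjacency set** of genes over all products,
compared with the master's.  This is the only annotation-level
criterion that is computable from the data alone, and it explains why
gene-free excisions leave the order "unchanged": a subcircle that
contains no genes removes no gene adjacency.  `genes_affected` lists
genes whose intervals overlap a repeat copy (not the inter-copy
segment) — matching how single genes sitting at repeat loci are
reported in published tables.

Pairwise gene-order distances are offered under two labelled metrics:
**breakpoint** (adjacencies of one order absent from the other, under
circular, reflection-aware comparison) and **inversion** (minimum
signed inversions, exact by breadth-first search over canonical
circular permutations for up to 12 shared genes; larger instances get a
documented lower/upper bound pair — the lower bound from breakpoints/2,
the upper from a greedy breakpoint-reducing search).

## Composition and introns

`partition_genome()` divides the circle into exon, intron and spacer
tracks with precedence exon > intron > spacer and union semantics, so
the three fractions sum to the genome length *exactly* on every input
(a tested invariant).  `profile_spacers()` decomposes the spacer track
into ORF content (start-to-stop frames ≥ 100 codons by default — the
threshold is unstated in published surveys, so this conventional value
is configurable and derived ORF percentages should be read as
indicative), perfect microsatellites (motif lengths 1–6 bp at minimum
tandem counts 10, 6, 5, 5, 5, 5 — the common microsatellite survey
convention, also configurable), and dispersed-repeat coverage from the
repeat finder.  Each category is merged base coverage clipped to the
spacer track, so nothing is double-counted within a category.
Spacer fractions that require external reference genomes
(nuclear-origin, plastid-origin, pseudogene content) are out of scope
and deliberately absent rather than zero.

Intron inventories use the standard nomenclature
`<gene>i<position><group>` (e.g. `cox1i44g2`): host gene, insertion
position in the spliced coding sequence, and intron group.  Group
membership (I vs II) is not inferred from RNA structure; it comes from
the packaged reference catalog keyed by gene + insertion site, and
introns absent from the catalog are named from their computed insertion
position with group `unknown` and flagged novel.

## The synthetic data generator

`generate_genome()` emulates the architecture these analyses consume: a
circular genome (default 50 kb) with non-overlapping protein-coding
genes (default 30, 300–1500 bp, ATG…stop codon structure, optional
single introns at 0.3 per gene), GC fraction 0.45, and repeat pairs
planted in intergenic spacers, the second copy diverged by seeded point
mutations and reverse-complemented for inverted pairs.
`simulate_read_pairs()` draws 2×150 bp inward-facing pairs with
Normal(350, 35) inserts truncated to [300, 490], uniform circular
positions and random orientation, at 300× coverage by default —
matching the short-insert PCR-free sequencing design of the surveys
this package models — from a molecule pool mixing the master circle
with recombinant product molecules at configured fractions (direct-pair
products sampled proportionally to their lengths).  Sequencing error is
i.i.d. substitution at 0.002 per base; there is no indel or quality
model, because the classifier thresholds are identity-based, matching
the published identity-threshold procedure.  Base qualities are written
as a constant.

Everything is deterministic given the config seed (byte-identical
FASTA/GFF3/FASTQ on reruns), and every read pair carries its source
molecule in a truth channel, so classification can be scored against
planted fractions.  What the generator does **not** emulate — real
flank homology structure, heteroplasmy gradients, chimeric or
duplicate reads, coverage waves — bounds what passing tests show: they
demonstrate correctness of the computation under the stated model, not
robustness to every artefact of real libraries.

## Numerical and design choices

* Internal coordinates are 0-based half-open on the circle; an interval
  wraps iff `start >= end`.  GFF3/GenBank stay 1-based inclusive on
  disk; origin-spanning features are one wrapping interval internally
  and a two-segment join externally.
* Ambiguity codes other than `N` are rejected at parse time so identity
  arithmetic stays well defined; `N` never matches anything.
* Rates are rounded to two decimals only at the reporting edge; cohort
  medians use the midpoint convention for even counts.
* The packaged survey fixture stores percentages exactly as printed and
  treats read counts as authoritative; the loader revalidates every
  printed rate against the counts at the printed precision and flags
  the one published row whose percentages do not sum to 100.
* Ties everywhere (repeat canonical ordering, best-member assignment,
  duplicate gene labels) are broken deterministically, so all outputs
  are byte-stable under identical configs; the pipeline stamps outputs
  with a config hash and reuses cached outputs when it matches.
* Test and acceptance problem sizes — 50 kb genomes at 300× for
  parameter recovery (twenty seeded replicates), fifty ≤ 3 kb genomes
  for oracle equivalence — were chosen as the smallest scales at which
  the binomial error bands and the exhaustive oracle remain meaningful
  for the survey's sequencing design.

## A worked example

```{r example, eval = FALSE}
library(mitorecomb)

sim <- simulation_config(
  genome_length = 50000, coverage = 300,
  planted_repeats = data.frame(length = 150, direction = "direct",
                               identity_pct = 100, min_copy_gap = 5000),
  alt_fraction = 0.1, seed = 7)
res <- run_pipeline(pipeline_config(sim_config = sim, out_dir = "demo", seed = 7))
res$events[, c("length_bp", "direction", "master_count", "alt_count", "rate_pct")]

# the published 26-event survey and its cohort statistics
summarize_events(load_table2_fixture())
```

## Known limitations

* Indel-containing repeats are reported as adjacent ungapped pairs.
* Only pairwise repeats are modelled; a family of three or more copies
  is emitted as all qualifying pairs.
* The conformation mixture is summarised by one rate per repeat; there
  is no probabilistic genotyping of multi-repeat joint conformations,
  no long-read support, and no per-tissue inference.
* Gene-order "changed/unchanged" calls depend on the adjacency-set
  definition above; published tables do not state their rule, so
  agreement with them is expected but not provable without the
  deposited assemblies.
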