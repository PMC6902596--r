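# mitorecomb

Repeat-mediated recombination analysis for circular mitochondrial
genomes.

Plant mitochondrial genomes assemble as a single circular *master*
molecule, but dispersed repeats can mediate intramolecular homologous
recombination, so several genome conformations may coexist in one
plant.  In liverworts this recombination is rare and gene order is
strongly conserved, which makes the minority conformations detectable
only by counting individual read pairs that span a recombinant
junction.  `mitorecomb` is for organellar-genome researchers who want
that assay as reusable, tested R functions: repeat discovery on a
circle, junction reference panels, read-pair classification, per-repeat
rate estimation, predicted recombinant gene orders, genome composition
and intron inventories, plus a fully ground-truthed synthetic-data
generator.

## The core computation

For each assayable repeat pair (aligned length 50–250 bp at ≥ 85 %
identity, copies disjoint — the window a 2×150 bp, ~350 bp-insert
library can interrogate), a reference panel is built from the two
*original* junctions and the *recombinant* junctions, each member being

```
up-flank (≤200 bp) + repeat copy + down-flank (≤200 bp)
```

— 4 members when the copies are identical, 8 when they have diverged
(four crossover + two conversion products).  A read pair supports a
member iff both mates align end-to-end, inward-facing, at ≥ 98 %
identity, with the pair footprint reaching ≥ 50 bp into both flanks.
Pairs whose best support ties between the original and recombinant
classes are ambiguous and discarded.  The per-repeat recombination rate
is

&nbsp;&nbsp;&nbsp;&nbsp;rate = 100 · alt / (master + alt)

Direct-repeat recombination excises the inter-copy segment as a
subcircle; inverted-repeat recombination inverts it.  Gene order is
called *changed* iff the canonical signed circular adjacency set over
all products differs from the master's; gene-order distances are
available as breakpoint counts or exact minimum inversion counts (BFS,
≤ 12 genes).

## Worked example

Simulate a 20 kb circular mitogenome with one planted 150 bp direct
repeat whose recombinant conformation carries 20 % of molecules, then
run the whole pipeline:

```r
library(mitorecomb)

sim <- simulation_config(
  genome_length = 20000, n_genes = 12, coverage = 120,
  planted_repeats = data.frame(length = 150, direction = "direct",
                               identity_pct = 100, min_copy_gap = 2000),
  alt_fraction = 0.2, base_error_rate = 0, seed = 42)
res <- run_pipeline(pipeline_config(sim_config = sim, out_dir = "demo",
                                    seed = 42))
res$events[, c("length_bp", "direction", "master_count", "alt_count",
               "rate_pct", "gene_order_state")]
#>   length_bp direction master_count alt_count rate_pct gene_order_state
#> 1       150    direct           63        15    19.23          changed
```

The planted repeat is recovered exactly; 63 read pairs anchor the
master junctions and 15 the excision junctions, estimating the
recombinant fraction at 19.23 % (planted truth: 20 %, binomial noise at
this depth ≈ ±4.5 points).  The outputs land in `demo/` as `events.tsv`
(one row per repeat with read support), `summary.json`,
`composition.tsv`, `introns.tsv` and `distances.tsv`, each stamped with
a config hash.

The package also ships a machine-readable transcription of a published
26-event liverwort recombination survey:

```r
summarize_events(load_table2_fixture())
#> Recombination summary: 26 events, 16 species
#>   rates: median 4.45%, range 0.67-60.00%
#>   repeats: mean 103 bp, 10 (38%) > 100 bp; small-repeat median rate 11.46%
#>   gene order changed after 12 events
```

Half the events (12/26) change gene order; 8 of the 10 inverted-repeat
events do, versus 4 of 16 direct-repeat events, while direct events
affect genes more often (62.5 % vs 30 %).

## Documentation

The methods vignette (`vignettes/mitogenome-recombination.Rmd`) gives
the full model: panel construction, the classification rule and its
seed-anchoring guarantees, the ungapped extension semantics of the
repeat finder and its brute-force oracle, the adjacency-set definition
of gene-order change, composition/intron profiling conventions, what
the simulator does and does not emulate, and known limitations.
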