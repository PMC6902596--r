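Package: mitorecomb
Title: Repeat-Mediated Recombination in Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the structural dynamics of circular
    organellar genomes, with an emphasis on liverwort mitogenomes.
    Detects dispersed direct and inverted repeat pairs on circular
    sequences, screens paired-end reads for evidence of repeat-mediated
    homologous recombination using master/alternative junction reference
    panels, estimates per-repeat recombination rates, predicts the
    recombinant genome structures and their gene-order consequences
    (inversions and excision subcircles, breakpoint and inversion
    distances), partitions genomes into exonic, intronic and spacer
    fractions with ORF, dispersed-repeat and microsatellite content, and
    builds intron presence/absence inventories under standard intron
    nomenclature.  Includes a synthetic-data generator that emulates
    annotated circular mitogenomes with planted repeats and simulates
    paired-end reads from mixtures of master-circle and recombinant
    molecules, providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
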