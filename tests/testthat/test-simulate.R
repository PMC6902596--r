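test_that("config validation rejects inconsistent settings", {
  expect_error(simulation_config(alt_fraction = 0.5), "length")
  expect_error(simulation_config(
    planted_repeats = data.frame(length = 40L, direction = "direct",
                                 identity_pct = 100, min_copy_gap = 100L)),
    ">= 50")
  expect_error(simulation_config(
    planted_repeats = data.frame(length = 100L, direction = "direct",
                                 identity_pct = 100, min_copy_gap = 100L),
    alt_fraction = 1.2), "alt_fraction")
  expect_error(simulation_config(gc_fraction = 1.4), "gc_fraction")
  expect_error(simulation_config(read_length = 400L), "read_length")
  # infeasible packing is a capacity error
  expect_error(generate_genome(simulation_config(genome_length = 5000L,
                                                 n_genes = 20L)), "capacity")
})

test_that("generation is deterministic and byte-identical under a fixed seed", {
  cfg <- simulation_config(genome_length = 12000L, n_genes = 8L,
                           planted_repeats = data.frame(
                             length = 100L, direction = "inverted",
                             identity_pct = 95, min_copy_gap = 2000L),
                           alt_fraction = 0.1, coverage = 20, seed = 81L)
  g1 <- generate_genome(cfg); g2 <- generate_genome(cfg)
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_identical(features_table(g1$genome), features_table(g2$genome))
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  write_genome(g1$genome, file.path(d1, "g.fasta"), file.path(d1, "g.gff3"))
  write_genome(g2$genome, file.path(d2, "g.fasta"), file.path(d2, "g.gff3"))
  expect_identical(readLines(file.path(d1, "g.fasta")),
                   readLines(file.path(d2, "g.fasta")))
  expect_identical(readLines(file.path(d1, "g.gff3")),
                   readLines(file.path(d2, "g.gff3")))
  s1 <- simulate_read_pairs(g1$genome, g1$truth, cfg)
  s2 <- simulate_read_pairs(g2$genome, g2$truth, cfg)
  expect_identical(s1$reads, s2$reads)
})

test_that("a repeat-free genome contains no detectable repeat pairs", {
  cfg <- simulation_config(genome_length = 15000L, n_genes = 10L, seed = 82L)
  g <- generate_genome(cfg)$genome
  expect_equal(nrow(find_repeat_pairs(g)), 0)
})

test_that("read-pair count follows the coverage formula", {
  # coverage 100 on a 50 kb genome: floor(100 * 50000 / 300) = 16666
  cfg <- simulation_config(genome_length = 5000L, n_genes = 4L,
                           gene_length_range = c(300L, 600L),
                           coverage = 30, seed = 83L)
  g <- generate_genome(cfg)
  s <- simulate_read_pairs(g$genome, g$truth, cfg)
  expect_equal(nrow(s$reads), floor(30 * 5000 / (2 * 150)))
  expect_equal(floor(100 * 50000 / (2 * 150)), 16666)
  # provenance: every read pair maps to exactly one molecule
  expect_equal(length(s$truth$read_provenance), nrow(s$reads))
  expect_true(all(s$reads$source_molecule %in% s$truth$molecule_pool$id))
  expect_false(any(duplicated(names(s$truth$read_provenance))))
  # error: zero pairs
  cfg0 <- simulation_config(genome_length = 5000L, n_genes = 4L,
                            gene_length_range = c(300L, 600L),
                            coverage = 0.01, seed = 83L)
  expect_error(simulate_read_pairs(g$genome, g$truth, cfg0), "zero read pairs")
})

test_that("planted inverted repeat at 95% identity is recovered by the finder", {
  cfg <- simulation_config(genome_length = 20000L, n_genes = 10L,
                           planted_repeats = data.frame(
                             length = 200L, direction = "inverted",
                             identity_pct = 95, min_copy_gap = 3000L),
                           seed = 84L)
  gen <- generate_genome(cfg)
  rp <- find_repeat_pairs(gen$genome)
  rp <- rp[rp$aligned_length >= 150, ]
  expect_equal(nrow(rp), 1)
  expect_equal(rp$direction, "inverted")
  # identity within 1 point of planted (edit placement may shift ends)
  expect_lt(abs(rp$identity_pct - 95), 1)
  tp <- gen$truth$planted_pairs
  expect_lte(abs(rp$copy1_start - tp$copy1_start), 10)
  expect_lte(abs(rp$copy2_start - tp$copy2_start), 10)
})

test_that("reads from the master only never support the alternative", {
  cfg <- simulation_config(genome_length = 15000L, n_genes = 8L,
                           planted_repeats = data.frame(
                             length = 150L, direction = "direct",
                             identity_pct = 100, min_copy_gap = 3000L),
                           alt_fraction = 0, coverage = 60,
                           base_error_rate = 0, seed = 85L)
  gen <- generate_genome(cfg)
  sim <- simulate_read_pairs(gen$genome, gen$truth, cfg)
  expect_true(all(sim$reads$source_molecule == "master"))
  panel <- build_reference_panel(gen$genome, gen$truth$planted_pairs, 1)
  cnt <- classify_read_pairs(panel, sim$reads)
  expect_equal(cnt$alternative_pairs, 0)
})
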