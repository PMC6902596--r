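# small genome with genes at known places and an assayable repeat pair
structured_genome <- function(direction = "inverted", genes_between = 2,
                              seed = 61L) {
  cfg <- simulation_config(genome_length = 15000L, n_genes = 8L,
                           intron_rate = 0,
                           planted_repeats = data.frame(
                             length = 120L, direction = direction,
                             identity_pct = 100, min_copy_gap = 2000L),
                           seed = seed)
  gen <- generate_genome(cfg)
  list(genome = gen$genome, pairs = gen$truth$planted_pairs)
}

test_that("gene order extraction sorts by start and uses strand signs", {
  feats <- list(
    mt_feature("a", "gene", circ_interval(100, 200, 1000), "+", "a"),
    mt_feature("b", "gene", circ_interval(300, 400, 1000), "+", "b"),
    mt_feature("c", "gene", circ_interval(500, 600, 1000), "+", "c"))
  g <- annotated_genome("ord", random_seq(1000, seed = 62), "circular", feats)
  o <- extract_gene_order(g)
  expect_equal(o$labels, c("a", "b", "c"))
  expect_equal(o$signs, c(1, 1, 1))
  # a gene spanning the origin appears once, ordered by its start
  feats2 <- c(feats, list(mt_feature("w", "gene", circ_interval(950, 20, 1000), "-", "w")))
  o2 <- extract_gene_order(annotated_genome("ord2", random_seq(1000, seed = 63),
                                            "circular", feats2))
  expect_equal(o2$labels, c("a", "b", "c", "w"))
  expect_equal(o2$signs[4], -1)
  # empty include set rejected
  expect_error(extract_gene_order(g, include_kinds = "rRNA"), "no features")
})

test_that("inverted-pair recombination reverses and sign-flips the inter-copy genes", {
  sg <- structured_genome("inverted")
  out <- apply_recombination(sg$genome, sg$pairs, 1)
  expect_equal(length(out$product_genomes), 1)
  master <- extract_gene_order(sg$genome)
  prod <- out$products[[1]]
  # hand-computed permutation: genes between the copies reversed, signs flipped
  L <- sg$genome$length
  c1e <- sg$pairs$copy1_end[1]; c2s <- sg$pairs$copy2_start[1]
  ft <- features_table(sg$genome)
  ft <- ft[ft$kind == "gene", ]
  in_arc <- ((ft$start - c1e) %% L) < ((c2s - c1e) %% L)
  arc_genes <- ft$gene_name[in_arc][order((ft$start[in_arc] - c1e) %% L)]
  if (length(arc_genes) >= 1) {
    expected_labels <- c(rev(arc_genes),
                         ft$gene_name[!in_arc][order((ft$start[!in_arc] - c1e) %% L)])
    # compare as circular sequences starting from the same gene
    rot_to <- function(v, x) { i <- match(x, v); c(v[i:length(v)], v[seq_len(i - 1)]) }
    expect_equal(rot_to(prod$labels, expected_labels[1]), expected_labels)
    # arc genes flipped sign, others unchanged
    for (gn in arc_genes) {
      expect_equal(prod$signs[match(gn, prod$labels)],
                   -master$signs[match(gn, master$labels)])
    }
    expect_equal(out$gene_order_state, "changed")
  }
  # gene multiset conserved
  expect_setequal(prod$labels, master$labels)
  # sequence length conserved
  expect_equal(nchar(out$product_genomes[[1]]$sequence), L)
})

test_that("inverted-pair recombination is an involution", {
  sg <- structured_genome("inverted", seed = 64L)
  out1 <- apply_recombination(sg$genome, sg$pairs, 1)
  out2 <- apply_recombination(out1$product_genomes[[1]], sg$pairs, 1)
  expect_equal(out2$product_genomes[[1]]$sequence, sg$genome$sequence)
  expect_equal(canonical_gene_order(out2$products[[1]]),
               canonical_gene_order(extract_gene_order(sg$genome)))
})

test_that("direct-pair recombination excises a subcircle conserving genes", {
  sg <- structured_genome("direct", seed = 65L)
  master <- extract_gene_order(sg$genome)
  out <- apply_recombination(sg$genome, sg$pairs, 1)
  expect_equal(length(out$product_genomes), 2)
  # crossover resolution conserves total bp: each product keeps one copy
  lens <- vapply(out$product_genomes, function(g) g$length, 0L)
  expect_equal(sum(lens), sg$genome$length)
  # gene multiset conserved across products
  prod_labels <- unlist(lapply(out$products, `[[`, "labels"))
  expect_setequal(prod_labels, master$labels)
  expect_equal(length(prod_labels), length(master$labels))
})

test_that("a gene-free excision leaves the adjacency set unchanged", {
  # plant a direct pair whose inter-copy arc contains no genes: build a
  # genome with all genes clustered in one half and copies in the other
  set.seed(66)
  seq <- random_seq(8000)
  feats <- list(
    mt_feature("a", "gene", circ_interval(100, 400, 8000), "+", "a"),
    mt_feature("b", "gene", circ_interval(600, 900, 8000), "-", "b"),
    mt_feature("c", "gene", circ_interval(1100, 1400, 8000), "+", "c"))
  seq <- plant_copy(seq, 4001, 100, 6001)
  g <- annotated_genome("nf", seq, "circular", feats)
  pr <- find_repeat_pairs(g)
  pr <- select_assayable_repeats(pr)
  expect_equal(nrow(pr), 1)
  out <- apply_recombination(g, pr, 1)
  expect_equal(out$gene_order_state, "unchanged")
  expect_equal(length(out$genes_affected), 0)
})

test_that("genes overlapping a repeat copy are reported as affected", {
  set.seed(67)
  seq <- random_seq(8000)
  seq <- plant_copy(seq, 2001, 150, 6001)
  feats <- list(
    mt_feature("cob", "gene", circ_interval(2100, 2400, 8000), "+", "cob"),
    mt_feature("x", "gene", circ_interval(4000, 4300, 8000), "+", "x"))
  g <- annotated_genome("af", seq, "circular", feats)
  pr <- select_assayable_repeats(find_repeat_pairs(g))
  expect_equal(nrow(pr), 1)
  out <- suppressWarnings(apply_recombination(g, pr, 1))
  expect_true("cob" %in% out$genes_affected)
  expect_false("x" %in% out$genes_affected)
})

test_that("rearrangement distances behave as metrics and match the BFS oracle", {
  o1 <- gene_order("g1", letters[1:8], rep(1L, 8))
  expect_equal(as.integer(rearrangement_distance(o1, o1, "breakpoint")), 0)
  expect_equal(as.integer(rearrangement_distance(o1, o1, "inversion")), 0)
  # one segment sign-reversed: inversion distance 1
  o2 <- gene_order("g2", c("a", "b", "e", "d", "c", "f", "g", "h"),
                   c(1L, 1L, -1L, -1L, -1L, 1L, 1L, 1L))
  expect_equal(as.integer(rearrangement_distance(o1, o2, "inversion")), 1)
  expect_equal(as.integer(rearrangement_distance(o2, o1, "inversion")), 1)
  # two non-overlapping random inversions, distance verified by BFS oracle
  set.seed(68)
  for (rep in 1:5) {
    labs <- letters[1:10]; sgn <- rep(1L, 10)
    i <- sort(sample(2:5, 2)); j <- sort(sample(7:10, 2))
    l2 <- labs; s2 <- sgn
    l2[i[1]:i[2]] <- rev(l2[i[1]:i[2]]); s2[i[1]:i[2]] <- -rev(s2[i[1]:i[2]])
    l2[j[1]:j[2]] <- rev(l2[j[1]:j[2]]); s2[j[1]:j[2]] <- -rev(s2[j[1]:j[2]])
    oA <- gene_order("A", labs, sgn); oB <- gene_order("B", l2, s2)
    want <- oracle_inversion_distance(labs, sgn, l2, s2)
    got <- as.integer(rearrangement_distance(oA, oB, "inversion"))
    expect_equal(got, want)
    expect_equal(want, 2L)
    # breakpoint <= 2 x inversion distance
    bk <- as.integer(rearrangement_distance(oA, oB, "breakpoint"))
    expect_lte(bk, 2L * got)
    expect_gte(bk, 1L)
  }
  # disjoint label sets are an error
  expect_error(rearrangement_distance(gene_order("x", "a", 1L),
                                      gene_order("y", "b", 1L)), "no labels")
})

test_that("distances compare orders up to rotation and reflection", {
  o1 <- gene_order("g1", letters[1:6], rep(1L, 6))
  rot <- gene_order("g3", c("d", "e", "f", "a", "b", "c"), rep(1L, 6))
  refl <- gene_order("g4", rev(letters[1:6]), rep(-1L, 6))
  expect_equal(as.integer(rearrangement_distance(o1, rot, "breakpoint")), 0)
  expect_equal(as.integer(rearrangement_distance(o1, refl, "breakpoint")), 0)
  expect_equal(as.integer(rearrangement_distance(o1, rot, "inversion")), 0)
  expect_equal(as.integer(rearrangement_distance(o1, refl, "inversion")), 0)
})
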