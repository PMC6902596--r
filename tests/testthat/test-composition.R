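test_that("partition respects precedence and conserves total length", {
  # zero features: everything is spacer
  g0 <- annotated_genome("z", random_seq(500, seed = 71))
  p0 <- partition_genome(g0)
  expect_equal(p0$spacer_bp, 500)
  # 10 kb circle, one gene of two 300 bp exons and one 400 bp intron
  set.seed(72)
  feats <- list(
    mt_feature("g", "gene", circ_interval(1000, 2000, 10000), "+", "nad2"),
    mt_feature("e1", "exon", circ_interval(1000, 1300, 10000), "+", "nad2",
               list(parent = "g")),
    mt_feature("i1", "intron", circ_interval(1300, 1700, 10000), "+", "nad2",
               list(parent = "g")),
    mt_feature("e2", "exon", circ_interval(1700, 2000, 10000), "+", "nad2",
               list(parent = "g")))
  g <- annotated_genome("p", random_seq(10000), "circular", feats)
  p <- partition_genome(g)
  expect_equal(p$exon_bp, 600)
  expect_equal(p$intron_bp, 400)
  expect_equal(p$spacer_bp, 9000)
  # two genes overlapping by 50 bp on opposite strands: union semantics
  feats2 <- list(
    mt_feature("a", "gene", circ_interval(100, 300, 1000), "+", "a"),
    mt_feature("b", "gene", circ_interval(250, 450, 1000), "-", "b"))
  g2 <- annotated_genome("ov", random_seq(1000, seed = 73), "circular", feats2)
  p2 <- partition_genome(g2)
  expect_equal(p2$exon_bp, 350)
  expect_equal(p2$exon_bp + p2$intron_bp + p2$spacer_bp, p2$total_bp)
})

test_that("partition conservation holds on generated genomes and percents recompute", {
  for (seed in c(74L, 75L)) {
    cfg <- simulation_config(genome_length = 12000L, n_genes = 8L,
                             intron_rate = 0.5, seed = seed)
    g <- generate_genome(cfg)$genome
    p <- partition_genome(g)
    expect_equal(p$exon_bp + p$intron_bp + p$spacer_bp, g$length)
    expect_gt(p$intron_bp, 0)
    expect_equal(p$exon_pct, 100 * p$exon_bp / p$total_bp)
  }
})

test_that("planted ORFs are detected at their coordinates", {
  set.seed(76)
  # spacer of 3000 random bases with a planted 450 bp ORF
  backbone <- random_seq(3000)
  orf_codons <- paste(sample(mitorecomb:::SENSE_CODONS, 148, replace = TRUE),
                      collapse = "")
  orf <- paste0("ATG", orf_codons, "TAA")
  expect_equal(nchar(orf), 450)
  seq <- paste0(substring(backbone, 1, 1000), orf, substring(backbone, 1451, 3000))
  g <- annotated_genome("orf", seq)
  prof <- profile_spacers(g)
  expect_gte(prof$spacer_orf_bp, 450)
  orfs <- find_orfs(seq, min_codons = 100)
  hit <- orfs[orfs$strand == "+" & orfs$start <= 1001 & orfs$end >= 1450, ]
  expect_gte(nrow(hit), 1)
})

test_that("SSR tract arithmetic and empty repeat content", {
  seq <- paste0(random_seq(400, seed = 77), strrep("AT", 14), random_seq(400))
  ssrs <- find_ssrs(seq)
  at <- ssrs[ssrs$motif %in% c("AT", "TA"), ]
  expect_equal(nrow(at), 1)
  expect_equal(at$end - at$start + 1, 28)
  g <- annotated_genome("ssr", seq)
  prof <- profile_spacers(g)
  expect_gte(prof$spacer_ssr_bp, 28)
  # genome with no repeat pairs has zero spacer repeat content
  expect_equal(prof$spacer_repeat_bp, 0)
})

test_that("intron names round-trip through the standard nomenclature", {
  expect_equal(intron_name("cox1", 44, "g2"), "cox1i44g2")
  p <- parse_intron_name("cox1i44g2")
  expect_equal(p$gene, "cox1")
  expect_equal(p$pos, 44)
  expect_equal(p$group, "g2")
  p2 <- parse_intron_name("nad4Li100g2")
  expect_equal(p2$gene, "nad4L")
  expect_equal(p2$pos, 100)
  expect_error(parse_intron_name("notanintron"), "parse")
  # catalog is loadable and self-consistent
  ct <- load_intron_catalog()
  expect_true(all(ct$name == mapply(intron_name, ct$gene, ct$insertion_pos, ct$group)))
})

intron_genome <- function(id, gene_defs, L = 6000L, seed = 78L) {
  # gene_defs: list of list(gene, exon1_len, intron_len, exon2_len, at)
  set.seed(seed)
  seq <- random_seq(L)
  feats <- list(); pos <- 200L
  for (d in gene_defs) {
    gid <- paste0(id, "_", d$gene)
    tot <- d$e1 + d$ilen + d$e2
    feats <- c(feats, list(
      mt_feature(gid, "gene", circ_interval(pos, pos + tot, L), "+", d$gene),
      mt_feature(paste0(gid, "_e1"), "exon", circ_interval(pos, pos + d$e1, L),
                 "+", d$gene, list(parent = gid)),
      mt_feature(paste0(gid, "_i1"), "intron",
                 circ_interval(pos + d$e1, pos + d$e1 + d$ilen, L), "+", d$gene,
                 list(parent = gid)),
      mt_feature(paste0(gid, "_e2"), "exon",
                 circ_interval(pos + d$e1 + d$ilen, pos + tot, L), "+", d$gene,
                 list(parent = gid))))
    pos <- pos + tot + 300L
  }
  annotated_genome(id, seq, "circular", feats)
}

test_that("intron inventory matches catalog names and per-genome totals", {
  shared <- list(list(gene = "cox1", e1 = 44L, ilen = 300L, e2 = 400L),
                 list(gene = "cob", e1 = 824L, ilen = 250L, e2 = 100L),
                 list(gene = "nad4L", e1 = 100L, ilen = 200L, e2 = 80L))
  extra <- list(list(gene = "rrn18", e1 = 1065L, ilen = 150L, e2 = 200L))
  gA <- intron_genome("spA", c(shared, extra), L = 9000L)
  gB <- intron_genome("spB", shared, L = 7000L)
  inv <- build_intron_inventory(list(gA, gB))
  expect_equal(nrow(inv), 4)
  expect_equal(unname(attr(inv, "totals")), c(4L, 3L))
  expect_true(all(c("cox1i44g2", "cobi824g2", "nad4Li100g2", "rrn18i1065g2") %in%
                    inv$name))
  expect_false(any(inv$novel))
  expect_true(all(inv$spA))
  expect_equal(sum(inv$spB), 3)
  # an intron not in the catalog is flagged novel with group unknown
  gC <- intron_genome("spC", list(list(gene = "cox1", e1 = 61L, ilen = 120L,
                                       e2 = 150L)), L = 5000L)
  invC <- build_intron_inventory(list(gC))
  expect_true(invC$novel[1])
  expect_equal(invC$group[1], "unknown")
  expect_equal(invC$name[1], "cox1i61unknown")
  # empty genome set rejected
  expect_error(build_intron_inventory(list()), "no genomes")
})

test_that("insertion positions respect the coding strand", {
  # same physical layout on the minus strand: insertion position counts
  # spliced bases from the coding 5' end
  L <- 4000L
  set.seed(79)
  seq <- random_seq(L)
  feats <- list(
    mt_feature("g", "gene", circ_interval(1000, 1744, L), "-", "cox2"),
    mt_feature("e1", "exon", circ_interval(1000, 1400, L), "-", "cox2",
               list(parent = "g")),
    mt_feature("i1", "intron", circ_interval(1400, 1650, L), "-", "cox2",
               list(parent = "g")),
    mt_feature("e2", "exon", circ_interval(1650, 1744, L), "-", "cox2",
               list(parent = "g")))
  g <- annotated_genome("minus", seq, "circular", feats)
  gi <- mitorecomb:::genome_introns(g)
  # coding 5' exon is the downstream (higher-coordinate) one: 94 bp
  expect_equal(gi$insertion_pos, 94L)
})
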