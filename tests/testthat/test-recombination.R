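sim_case <- function(len = 150L, direction = "direct", identity = 100,
                     alt = 0, coverage = 100, err = 0, seed = 41L,
                     genome_length = 20000L) {
  cfg <- simulation_config(
    genome_length = genome_length, n_genes = 12L,
    planted_repeats = data.frame(length = len, direction = direction,
                                 identity_pct = identity, min_copy_gap = 3000L),
    alt_fraction = alt, coverage = coverage, base_error_rate = err, seed = seed)
  gen <- generate_genome(cfg)
  list(cfg = cfg, genome = gen$genome, truth = gen$truth,
       pairs = gen$truth$planted_pairs)
}

test_that("panel cardinality follows copy identity (4 identical, 8 diverged)", {
  cs <- sim_case(identity = 100, seed = 42L)
  p4 <- build_reference_panel(cs$genome, cs$pairs, 1)
  expect_equal(nrow(p4$members), 4)
  expect_equal(sum(p4$members$class == "original"), 2)
  expect_false(anyDuplicated(p4$members$label) > 0)

  cs8 <- sim_case(identity = 97, seed = 43L)
  p8 <- build_reference_panel(cs8$genome, cs8$pairs, 1)
  expect_equal(nrow(p8$members), 8)
  expect_equal(sum(p8$members$class == "original"), 2)
  expect_equal(sum(p8$members$class == "recombinant"), 6)
  # member sequences are flank + copy + flank
  for (k in seq_len(nrow(p8$members))) {
    expect_equal(nchar(p8$members$sequence[k]),
                 p8$members$flank_up[k] + cs8$pairs$aligned_length[1] +
                   p8$members$flank_down[k])
  }
})

test_that("recombinant junction member equals a manual excision construction", {
  cs <- sim_case(identity = 100, seed = 44L)
  g <- cs$genome; pr <- cs$pairs
  panel <- build_reference_panel(g, pr, 1, flank = 200)
  mem <- panel$members
  # manual excision of the inter-copy segment (plus copy 2): string
  # surgery on the raw sequence, independent of the panel code
  s <- g$sequence
  c1s <- pr$copy1_start[1]; c1e <- pr$copy1_end[1]; c2e <- pr$copy2_end[1]
  deleted <- paste0(substring(s, 1, c1e), substring(s, c2e + 1, nchar(s)))
  junction <- substring(deleted, c1s - 200 + 1, c1e + 200)
  expect_equal(mem$sequence[mem$label == "recomb_u1_r_d2"], junction)
})

test_that("flanks are truncated at the partner copy and flagged", {
  cs <- sim_case(seed = 45L)
  pr <- cs$pairs
  # shrink the copy gap artificially by moving copy2 next to copy1
  gap <- 80L
  pr$copy2_start <- pr$copy1_end + gap
  pr$copy2_end <- pr$copy2_start + pr$aligned_length
  pr <- structure(pr, class = c("repeat_pairs", "data.frame"),
                  genome_length = cs$genome$length, genome_id = cs$genome$id)
  panel <- build_reference_panel(cs$genome, pr, 1, flank = 200)
  expect_true(all(panel$members$truncated))
  m1 <- panel$members[panel$members$label == "original_1", ]
  expect_equal(m1$flank_down, gap)
})

test_that("master-only error-free reads give zero alternative support", {
  cs <- sim_case(alt = 0, coverage = 100, err = 0, seed = 46L)
  sim <- simulate_read_pairs(cs$genome, cs$truth, cs$cfg)
  panel <- build_reference_panel(cs$genome, cs$pairs, 1)
  cnt <- classify_read_pairs(panel, sim$reads)
  expect_equal(cnt$alternative_pairs, 0)
  expect_gt(cnt$master_pairs, 0)
  # conservation: classified + ambiguous + unmatched + skipped == total
  expect_equal(cnt$master_pairs + cnt$alternative_pairs + cnt$ambiguous_pairs +
                 cnt$unmatched_pairs + cnt$skipped_singletons, nrow(sim$reads))
  # per-member counts sum to the unambiguous classifications
  expect_equal(sum(cnt$per_member), cnt$master_pairs + cnt$alternative_pairs)
  # empty read set gives all-zero counts
  cnt0 <- classify_read_pairs(panel, sim$reads[0, , drop = FALSE])
  expect_equal(cnt0$master_pairs + cnt0$alternative_pairs + cnt0$ambiguous_pairs, 0)
})

test_that("a planted 10% recombinant fraction is recovered within binomial error", {
  cs <- sim_case(alt = 0.1, coverage = 200, err = 0, seed = 47L)
  sim <- simulate_read_pairs(cs$genome, cs$truth, cs$cfg)
  panel <- build_reference_panel(cs$genome, cs$pairs, 1)
  cnt <- classify_read_pairs(panel, sim$reads)
  nn <- cnt$master_pairs + cnt$alternative_pairs
  est <- cnt$alternative_pairs / nn
  se <- sqrt(0.1 * 0.9 / nn)
  expect_lt(abs(est - 0.1), 3 * se)
})

test_that("singleton mates are skipped and counted", {
  cs <- sim_case(alt = 0, coverage = 30, err = 0, seed = 48L)
  sim <- simulate_read_pairs(cs$genome, cs$truth, cs$cfg)
  reads <- sim$reads
  reads$mate2[1:5] <- ""
  panel <- build_reference_panel(cs$genome, cs$pairs, 1)
  cnt <- classify_read_pairs(panel, reads)
  expect_equal(cnt$skipped_singletons, 5)
})

test_that("raising thresholds never increases support counts", {
  cs <- sim_case(alt = 0.15, coverage = 150, err = 0.004, seed = 49L)
  sim <- simulate_read_pairs(cs$genome, cs$truth, cs$cfg)
  panel <- build_reference_panel(cs$genome, cs$pairs, 1)
  base <- classify_read_pairs(panel, sim$reads)
  for (args in list(list(min_identity = 99.5), list(min_flank_cov = 90))) {
    cnt <- do.call(classify_read_pairs,
                   c(list(panel = panel, reads = sim$reads), args))
    expect_lte(cnt$master_pairs, base$master_pairs)
    expect_lte(cnt$alternative_pairs, base$alternative_pairs)
  }
})

test_that("recombination rate arithmetic reproduces printed percentages", {
  expect_equal(recombination_rate(list(master_pairs = 30, alternative_pairs = 14)), 31.82)
  expect_equal(recombination_rate(list(master_pairs = 32, alternative_pairs = 48)), 60.00)
  expect_equal(recombination_rate(list(master_pairs = 7, alternative_pairs = 0)), 0.00)
  expect_error(recombination_rate(list(master_pairs = 0, alternative_pairs = 0)),
               "undefined")
})

test_that("rate is invariant under swapping the copy labels", {
  cs <- sim_case(alt = 0.2, coverage = 100, err = 0, seed = 50L)
  sim <- simulate_read_pairs(cs$genome, cs$truth, cs$cfg)
  pr <- cs$pairs
  swapped <- pr
  swapped[, c("copy1_start", "copy1_end")] <- pr[, c("copy2_start", "copy2_end")]
  swapped[, c("copy2_start", "copy2_end")] <- pr[, c("copy1_start", "copy1_end")]
  swapped <- structure(swapped, class = class(pr),
                       genome_length = attr(pr, "genome_length"),
                       genome_id = attr(pr, "genome_id"))
  r1 <- recombination_rate(classify_read_pairs(
    build_reference_panel(cs$genome, pr, 1), sim$reads))
  r2 <- recombination_rate(classify_read_pairs(
    build_reference_panel(cs$genome, swapped, 1), sim$reads))
  expect_equal(r1, r2)
})

test_that("single-event summaries degenerate sensibly", {
  ev <- structure(data.frame(species = "x", event_id = "e", length_bp = 80L,
                             identity_pct = 95, direction = "direct",
                             copy1_pos = "1-80", copy2_pos = "200-279",
                             master_count = 37L, master_pct = 92.5,
                             alt_count = 3L, alt_pct = 7.5, rate_pct = 7.5,
                             gene_order_state = "unchanged", genes_affected = "",
                             stringsAsFactors = FALSE),
                  class = c("recomb_events", "data.frame"))
  s <- summarize_events(ev)
  expect_equal(s$rate_median_pct, 7.5)
  expect_equal(s$rate_min_pct, 7.5)
  expect_equal(s$rate_max_pct, 7.5)
  expect_equal(s$n_events, 1)
})
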