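# Synthetic annotated circular mitogenomes with planted repeats, and
# paired-end read simulation from a mixture of master-circle and
# recombinant molecules.  Every stochastic choice is driven by the
# config seed, so identical configs give byte-identical outputs.

#' Simulation configuration
#'
#' Defaults emulate the sequencing design of liverwort mitogenome
#' surveys: 2x150 bp paired-end reads, ~350 bp inserts, deep coverage of
#' a gene-dense circular genome with dispersed repeats planted in
#' intergenic spacers.
#'
#' @param genome_length Circle size in bp (default 50000).
#' @param n_genes Number of protein-coding-like genes (default 30).
#' @param gene_length_range Min/max coding length in bp (default 300-1500;
#'   rounded to codons).
#' @param intron_rate Per-gene probability of carrying one intron.
#' @param gc_fraction GC content of the background sequence.
#' @param planted_repeats Data.frame with columns `length`, `direction`
#'   (`"direct"`/`"inverted"`), `identity_pct`, `min_copy_gap`; one row
#'   per planted repeat pair.
#' @param alt_fraction Numeric vector aligned with `planted_repeats`:
#'   fraction of molecules carrying the recombinant configuration of
#'   each repeat.
#' @param coverage Fold sequencing coverage (default 300).
#' @param read_length Read length in bp (default 150).
#' @param insert_mean,insert_sd Insert size distribution (default 350/35).
#' @param base_error_rate Per-base substitution error rate (default 0.002).
#' @param seed Integer seed driving all randomness.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 50000L, n_genes = 30L,
                              gene_length_range = c(300L, 1500L),
                              intron_rate = 0.3, gc_fraction = 0.45,
                              planted_repeats = NULL,
                              alt_fraction = numeric(0),
                              coverage = 300, read_length = 150L,
                              insert_mean = 350, insert_sd = 35,
                              base_error_rate = 0.002, seed = 1L) {
  if (is.null(planted_repeats)) {
    planted_repeats <- data.frame(length = integer(0), direction = character(0),
                                  identity_pct = numeric(0), min_copy_gap = integer(0))
  }
  if (!all(c("length", "direction", "identity_pct", "min_copy_gap") %in%
           names(planted_repeats)))
    stop("planted_repeats needs columns length, direction, identity_pct, min_copy_gap",
         call. = FALSE)
  if (length(alt_fraction) == 0L) alt_fraction <- rep(0, nrow(planted_repeats))
  stopifnot(length(alt_fraction) == nrow(planted_repeats))
  if (any(alt_fraction < 0 | alt_fraction > 1) || sum(alt_fraction) > 1)
    stop("alt_fraction values must lie in [0,1] and sum to at most 1", call. = FALSE)
  if (nrow(planted_repeats) && any(planted_repeats$length < 50L))
    stop("planted repeat lengths must be >= 50 bp", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction outside [0,1]", call. = FALSE)
  if (base_error_rate < 0 || base_error_rate > 1)
    stop("base_error_rate outside [0,1]", call. = FALSE)
  if (read_length > insert_mean) stop("read_length must not exceed insert_mean", call. = FALSE)
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 intron_rate = intron_rate, gc_fraction = gc_fraction,
                 planted_repeats = planted_repeats, alt_fraction = alt_fraction,
                 coverage = coverage, read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 base_error_rate = base_error_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

SENSE_CODONS <- setdiff(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")), 1L, paste, collapse = ""),
                        c("TAA", "TAG", "TGA"))

random_coding <- function(n_codons) {
  paste0("ATG", paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

#' Generate a synthetic annotated circular mitogenome
#'
#' Genes (with optional single introns) are placed without overlap
#' around the circle; repeat pairs are planted in intergenic spacers,
#' the second copy diverged to the requested identity by point
#' mutations and reverse-complemented for inverted pairs.
#'
#' @param config A [simulation_config()].
#' @return List with elements `genome` (an [annotated_genome()]) and
#'   `truth` (class `simulation_truth`: `planted_pairs` as a
#'   `repeat_pairs` data.frame, plus the config).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$genome_length
  n <- config$n_genes
  min_gap <- 300L

  glen <- sample(seq(config$gene_length_range[1L], config$gene_length_range[2L], by = 3L),
                 n, replace = TRUE)
  has_intron <- stats::runif(n) < config$intron_rate
  ilen <- ifelse(has_intron, sample(200:600, n, replace = TRUE), 0L)
  total <- sum(glen + ilen)
  if (total + n * min_gap >= L)
    stop("capacity error: requested features exceed the genome length", call. = FALSE)

  fr <- stats::runif(n)
  extra <- L - total - n * min_gap
  gaps <- min_gap + floor(extra * fr / sum(fr))
  # pieces: gap1, gene1, gap2, gene2, ...
  parts <- character(0)
  feats <- list()
  pos <- 0L
  gene_windows <- matrix(integer(0), ncol = 2L)
  spacer_segs <- list()
  for (gi in seq_len(n)) {
    gap_seq <- random_dna(gaps[gi], config$gc_fraction)
    parts <- c(parts, gap_seq)
    spacer_segs[[length(spacer_segs) + 1L]] <- c(pos, pos + gaps[gi])
    pos <- pos + gaps[gi]
    strand <- sample(c("+", "-"), 1L)
    coding <- random_coding(glen[gi] %/% 3L)
    gid <- sprintf("gene%02d", gi)
    gname <- sprintf("g%02d", gi)
    if (has_intron[gi]) {
      ncod <- glen[gi] %/% 3L
      at <- sample(10:(ncod - 10L), 1L) * 3L    # codon boundary, bp into coding
      intron_seq <- random_dna(ilen[gi], config$gc_fraction)
      gene_seq <- paste0(substring(coding, 1L, at), intron_seq,
                         substring(coding, at + 1L, glen[gi]))
      span <- glen[gi] + ilen[gi]
      if (strand == "-") gene_seq <- dna_revcomp(gene_seq)
      # forward-coordinate layout of exon/intron within the gene
      if (strand == "+") {
        e1 <- c(0L, at); iv <- c(at, at + ilen[gi]); e2 <- c(at + ilen[gi], span)
      } else {
        e2r <- c(0L, glen[gi] - at); ivr <- c(glen[gi] - at, glen[gi] - at + ilen[gi])
        e1r <- c(glen[gi] - at + ilen[gi], span)
        e1 <- e1r; iv <- ivr; e2 <- e2r
      }
      feats <- c(feats, list(
        mt_feature(gid, "gene", circ_interval(pos, pos + span, L), strand, gname),
        mt_feature(paste0(gid, "_e1"), "exon",
                   circ_interval(pos + e1[1L], pos + e1[2L], L), strand, gname,
                   list(parent = gid)),
        mt_feature(paste0(gid, "_i1"), "intron",
                   circ_interval(pos + iv[1L], pos + iv[2L], L), strand, gname,
                   list(parent = gid)),
        mt_feature(paste0(gid, "_e2"), "exon",
                   circ_interval(pos + e2[1L], pos + e2[2L], L), strand, gname,
                   list(parent = gid))))
    } else {
      gene_seq <- if (strand == "-") dna_revcomp(coding) else coding
      span <- glen[gi]
      feats <- c(feats, list(
        mt_feature(gid, "gene", circ_interval(pos, pos + span, L), strand, gname)))
    }
    parts <- c(parts, gene_seq)
    gene_windows <- rbind(gene_windows, c(pos, pos + span))
    pos <- pos + span
  }
  tail_len <- L - pos
  if (tail_len > 0L) {
    parts <- c(parts, random_dna(tail_len, config$gc_fraction))
    spacer_segs[[length(spacer_segs) + 1L]] <- c(pos, L)
  }
  seq <- paste(parts, collapse = "")
  stopifnot(nchar(seq) == L)

  # plant repeats into spacer segments (20 bp margins from genes)
  margin <- 20L
  avail <- do.call(rbind, spacer_segs)
  avail[, 1L] <- avail[, 1L] + margin
  avail[, 2L] <- avail[, 2L] - margin
  avail <- avail[avail[, 2L] - avail[, 1L] > 0L, , drop = FALSE]
  pr <- config$planted_repeats
  planted <- list()
  for (ri in seq_len(nrow(pr))) {
    len <- pr$length[ri]
    wins <- take_spacer_window(avail, len)
    if (is.null(wins)) stop("capacity error: no spacer room for planted repeat ", ri,
                            call. = FALSE)
    avail <- wins$avail; src <- wins$window
    # target window at least min_copy_gap away from the source
    repeat {
      wint <- take_spacer_window(avail, len)
      if (is.null(wint))
        stop("capacity error: no spacer room for planted repeat ", ri, call. = FALSE)
      gap_ok <- min((wint$window[1L] - src[2L]) %% L,
                    (src[1L] - wint$window[2L]) %% L) >= pr$min_copy_gap[ri]
      if (gap_ok) { avail <- wint$avail; tgt <- wint$window; break }
      # rare: re-draw without replacing the rejected window
      avail <- wint$avail
    }
    src_seq <- substring(seq, src[1L] + 1L, src[1L] + len)
    n_mut <- round(len * (1 - pr$identity_pct[ri] / 100))
    copy_seq <- src_seq
    if (n_mut > 0L) {
      at <- sample.int(len, n_mut)
      ch <- strsplit(copy_seq, "")[[1L]]
      for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      copy_seq <- paste(ch, collapse = "")
    }
    placed <- if (pr$direction[ri] == "inverted") dna_revcomp(copy_seq) else copy_seq
    seq <- paste0(substring(seq, 1L, tgt[1L]), placed,
                  substring(seq, tgt[1L] + len + 1L, L))
    stopifnot(nchar(seq) == L)
    c1 <- src; c2 <- tgt
    a1 <- src_seq; a2 <- copy_seq
    if (c2[1L] < c1[1L]) { tmp <- c1; c1 <- c2; c2 <- tmp; tmp <- a1; a1 <- a2; a2 <- tmp }
    planted[[length(planted) + 1L]] <- data.frame(
      id = sprintf("planted%02d", ri),
      copy1_start = c1[1L], copy1_end = c1[2L],
      copy2_start = c2[1L], copy2_end = c2[2L],
      direction = pr$direction[ri],
      identity_pct = 100 * (len - n_mut) / len,
      aligned_length = len,
      score = MATCH_SCORE * (len - n_mut) + MISMATCH_SCORE * n_mut,
      aln1 = a1, aln2 = a2, stringsAsFactors = FALSE)
    feats <- c(feats, list(
      mt_feature(sprintf("planted%02d_c1", ri), "repeat",
                 circ_interval(c1[1L], c1[2L], L), "+", ""),
      mt_feature(sprintf("planted%02d_c2", ri), "repeat",
                 circ_interval(c2[1L], c2[2L], L), "+", "")))
  }

  genome <- annotated_genome(sprintf("sim%06d", config$seed), seq, "circular", feats)
  planted_pairs <- if (length(planted)) do.call(rbind, planted) else
    as.data.frame(empty_repeat_pairs(genome))
  planted_pairs <- structure(planted_pairs,
                             class = c("repeat_pairs", "data.frame"),
                             genome_length = L, genome_id = genome$id)
  truth <- structure(list(planted_pairs = planted_pairs, config = config,
                          molecule_pool = NULL, read_provenance = NULL),
                     class = "simulation_truth")
  list(genome = genome, truth = truth)
}

# pick a random window of width len inside the available spacer segments;
# returns the window and the availability table with it removed
take_spacer_window <- function(avail, len) {
  ok <- which(avail[, 2L] - avail[, 1L] >= len)
  if (!length(ok)) return(NULL)
  w <- avail[ok, 2L] - avail[ok, 1L] - len + 1L
  seg <- ok[sample.int(length(ok), 1L, prob = w)]
  off <- sample.int(avail[seg, 2L] - avail[seg, 1L] - len + 1L, 1L) - 1L
  start <- avail[seg, 1L] + off
  window <- c(start, start + len)
  left <- c(avail[seg, 1L], start)
  right <- c(window[2L], avail[seg, 2L])
  avail <- avail[-seg, , drop = FALSE]
  if (left[2L] - left[1L] > 0L) avail <- rbind(avail, left)
  if (right[2L] - right[1L] > 0L) avail <- rbind(avail, right)
  list(window = window, avail = avail[order(avail[, 1L]), , drop = FALSE])
}

#' Simulate paired-end reads from a master/recombinant molecule mixture
#'
#' The molecule pool is the master circle plus, for each planted repeat
#' with a positive alternative fraction, its recombinant product
#' molecule(s): the inversion circle for inverted repeats, or the
#' deleted circle plus excision subcircle (sampled proportionally to
#' their lengths) for direct repeats.  Fragments have normal insert
#' sizes truncated to `[2*read_length, insert_mean + 4*insert_sd]`,
#' uniform circular start positions and random orientation; per-base
#' substitution errors are i.i.d. at `base_error_rate`.  The number of
#' pairs is `floor(coverage * genome_length / (2 * read_length))`.
#'
#' @param genome An [annotated_genome()] from [generate_genome()].
#' @param truth The matching `simulation_truth`.
#' @param config The [simulation_config()].
#' @return List with `reads` (data.frame `id`, `mate1`, `mate2`,
#'   `source_molecule`) and `truth` updated with `molecule_pool` and
#'   `read_provenance`.
#' @export
simulate_read_pairs <- function(genome, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 7919L)
  L <- config$genome_length
  rl <- config$read_length
  n_pairs <- floor(config$coverage * L / (2 * rl))
  if (n_pairs < 1L) stop("coverage yields zero read pairs", call. = FALSE)

  pool <- data.frame(id = "master", seq = genome$sequence,
                     weight = 1 - sum(config$alt_fraction),
                     stringsAsFactors = FALSE)
  pairs <- truth$planted_pairs
  for (ri in seq_len(nrow(pairs))) {
    f <- config$alt_fraction[ri]
    if (f <= 0) next
    out <- suppressWarnings(apply_recombination(genome, pairs, ri))
    seqs <- vapply(out$product_genomes, `[[`, "", "sequence")
    w <- f * nchar(seqs) / sum(nchar(seqs))
    pool <- rbind(pool, data.frame(id = paste0(pairs$id[ri], "_alt",
                                               seq_along(seqs)),
                                   seq = seqs, weight = w,
                                   stringsAsFactors = FALSE))
  }

  counts <- as.vector(stats::rmultinom(1L, n_pairs, pool$weight))
  ins_min <- 2L * rl
  ins_max <- round(config$insert_mean + 4 * config$insert_sd)
  id_all <- character(0); m1_all <- character(0); m2_all <- character(0)
  src_all <- character(0)
  serial <- 0L
  for (mi in seq_len(nrow(pool))) {
    nm <- counts[mi]
    if (nm == 0L) next
    mol <- pool$seq[mi]; ml <- nchar(mol)
    mol2 <- paste0(mol, mol)
    starts <- sample.int(ml, nm, replace = TRUE) - 1L
    ins <- round(stats::rnorm(nm, config$insert_mean, config$insert_sd))
    ins <- pmin(pmax(ins, ins_min), min(ins_max, ml))
    frag <- substring(mol2, starts + 1L, starts + ins)
    flip <- stats::runif(nm) < 0.5
    if (any(flip)) frag[flip] <- dna_revcomp(frag[flip])
    m1 <- substring(frag, 1L, rl)
    m2 <- dna_revcomp(substring(frag, ins - rl + 1L, ins))
    ids <- sprintf("rd%07d", serial + seq_len(nm))
    serial <- serial + nm
    id_all <- c(id_all, ids); m1_all <- c(m1_all, m1); m2_all <- c(m2_all, m2)
    src_all <- c(src_all, rep(pool$id[mi], nm))
  }
  # sequencing errors: i.i.d. substitutions
  e <- config$base_error_rate
  if (e > 0) {
    mates <- c(m1_all, m2_all)
    nerr <- stats::rbinom(length(mates), rl, e)
    for (ii in which(nerr > 0L)) {
      ch <- strsplit(mates[ii], "")[[1L]]
      at <- sample.int(rl, nerr[ii])
      for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      mates[ii] <- paste(ch, collapse = "")
    }
    m1_all <- mates[seq_along(m1_all)]
    m2_all <- mates[length(m1_all) + seq_along(m2_all)]
  }
  reads <- data.frame(id = id_all, mate1 = m1_all, mate2 = m2_all,
                      source_molecule = src_all, stringsAsFactors = FALSE)
  truth$molecule_pool <- pool[, c("id", "weight")]
  truth$read_provenance <- stats::setNames(reads$source_molecule, reads$id)
  list(reads = reads, truth = truth)
}
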