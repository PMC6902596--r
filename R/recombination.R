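# Reference-panel construction and paired-end read classification: the
# core recombination assay.  For each assayable repeat a panel of
# original (master-circle) and recombinant junction sequences is built
# (repeat copy plus up to 200 bp flanks); read pairs are assigned to the
# conformation class whose member they match end-to-end.

#' Build the master/alternative reference panel for a repeat pair
#'
#' Each member is up-flank + repeat copy + down-flank, all read on one
#' strand (the second copy of an inverted pair is reverse-complemented
#' together with its flanks).  Two members are the in-genome originals.
#' For identical copies there are two recombinant junctions (flank
#' swaps), giving a panel of 4; for diverged copies the four crossover
#' products (both flank swaps x both copy sequences) and the two
#' conversion products (each original flank context carrying the other
#' copy's sequence) give a panel of 8.
#'
#' @param genome An [annotated_genome()].
#' @param pairs A `repeat_pairs` data.frame.
#' @param i Row of `pairs` to build the panel for.
#' @param flank Flank length in bp (default 200).  Flanks that would run
#'   into the partner copy are truncated at the copy boundary and the
#'   member flagged `truncated`.
#' @return An object of class `reference_panel` with elements `pair_id`,
#'   `flank`, and `members` (data.frame: `label`, `class`, `sequence`,
#'   `flank_up`, `flank_down`, `truncated`).
#' @export
build_reference_panel <- function(genome, pairs, i = 1L, flank = 200) {
  stopifnot(nrow(pairs) >= i)
  L <- genome$length
  if (attr(pairs, "genome_length") != L)
    stop("repeat pairs were found on a different genome length", call. = FALSE)
  flank <- as.integer(flank)
  if (flank < 1L) stop("flank must be >= 1", call. = FALSE)
  c1 <- pair_copy(pairs, i, "copy1")
  c2 <- pair_copy(pairs, i, "copy2")
  if (interval_overlap(c1, c2) > 0L)
    stop("pair '", pairs$id[i], "' has overlapping copies; not assayable",
         call. = FALSE)
  inverted <- pairs$direction[i] == "inverted"
  gapA <- (c2$start - c1$end) %% L   # arc copy1 -> copy2
  gapB <- (c1$start - c2$end) %% L   # arc copy2 -> copy1
  f_up1 <- min(flank, gapB); f_dn1 <- min(flank, gapA)
  if (inverted) { f_up2 <- min(flank, gapB); f_dn2 <- min(flank, gapA) }
  else          { f_up2 <- min(flank, gapA); f_dn2 <- min(flank, gapB) }
  truncated <- any(c(f_up1, f_dn1, f_up2, f_dn2) < flank)

  R1 <- subsequence(genome, c1)
  up1 <- if (f_up1) subsequence(genome, interval_from_span(c1$start - f_up1, f_up1, L)) else ""
  dn1 <- if (f_dn1) subsequence(genome, interval_from_span(c1$end, f_dn1, L)) else ""
  if (inverted) {
    R2 <- subsequence(genome, c2, strand = "-")
    up2 <- if (f_up2) subsequence(genome, interval_from_span(c2$end, f_up2, L), strand = "-") else ""
    dn2 <- if (f_dn2) subsequence(genome, interval_from_span(c2$start - f_dn2, f_dn2, L), strand = "-") else ""
  } else {
    R2 <- subsequence(genome, c2)
    up2 <- if (f_up2) subsequence(genome, interval_from_span(c2$start - f_up2, f_up2, L)) else ""
    dn2 <- if (f_dn2) subsequence(genome, interval_from_span(c2$end, f_dn2, L)) else ""
  }

  identical_copies <- pairs$identity_pct[i] >= 100 - 1e-9
  mk <- function(label, class, up, mid, dn) {
    data.frame(label = label, class = class, sequence = paste0(up, mid, dn),
               flank_up = nchar(up), flank_down = nchar(dn),
               truncated = truncated, stringsAsFactors = FALSE)
  }
  members <- rbind(mk("original_1", "original", up1, R1, dn1),
                   mk("original_2", "original", up2, R2, dn2))
  if (identical_copies) {
    members <- rbind(members,
                     mk("recomb_u1_r_d2", "recombinant", up1, R1, dn2),
                     mk("recomb_u2_r_d1", "recombinant", up2, R1, dn1))
  } else {
    members <- rbind(members,
                     mk("recomb_u1_r1_d2", "recombinant", up1, R1, dn2),
                     mk("recomb_u1_r2_d2", "recombinant", up1, R2, dn2),
                     mk("recomb_u2_r1_d1", "recombinant", up2, R1, dn1),
                     mk("recomb_u2_r2_d1", "recombinant", up2, R2, dn1),
                     mk("conv_u1_r2_d1", "recombinant", up1, R2, dn1),
                     mk("conv_u2_r1_d2", "recombinant", up2, R1, dn2))
  }
  structure(list(pair_id = pairs$id[i], flank = flank, members = members,
                 genome_id = genome$id),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel '%s': %d members (%d original, %d recombinant)>\n",
              x$pair_id, nrow(x$members), sum(x$members$class == "original"),
              sum(x$members$class == "recombinant")))
  invisible(x)
}

#' Classify read pairs against a reference panel
#'
#' A read pair supports a panel member when both mates align to it
#' end-to-end (no clipping), inward-facing, each mate at identity of at
#' least `min_identity` percent, the implied insert is at most
#' `max_insert`, and the united pair footprint covers at least
#' `min_flank_cov` bases of both the up- and down-flank.  Pairs
#' supporting members of both conformation classes are counted ambiguous
#' and excluded from both.
#'
#' @param panel A [build_reference_panel()] result.
#' @param reads Data.frame with `id`, `mate1`, `mate2` columns.
#' @param min_identity Per-mate identity threshold in percent (default 98).
#' @param min_flank_cov Minimum bp of each flank the pair footprint must
#'   cover (default 50).
#' @param max_insert Maximum implied insert in bp (default 1000).
#' @return A `support_counts` list: `pair_id`, `master_pairs`,
#'   `alternative_pairs`, `ambiguous_pairs`, `unmatched_pairs`,
#'   `skipped_singletons`, `per_member` (named counts over unambiguous
#'   pairs).
#' @export
classify_read_pairs <- function(panel, reads, min_identity = 98,
                                min_flank_cov = 50, max_insert = 1000) {
  members <- panel$members
  counts <- stats::setNames(integer(nrow(members)), members$label)
  res <- list(pair_id = panel$pair_id, master_pairs = 0L,
              alternative_pairs = 0L, ambiguous_pairs = 0L,
              unmatched_pairs = 0L, skipped_singletons = 0L,
              per_member = counts)
  class(res) <- "support_counts"
  if (is.null(reads) || nrow(reads) == 0L) return(res)

  ok <- !is.na(reads$mate1) & !is.na(reads$mate2) &
    nzchar(reads$mate1) & nzchar(reads$mate2)
  res$skipped_singletons <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  n <- nrow(reads)
  if (n == 0L) return(res)

  msubj <- Biostrings::DNAStringSet(members$sequence)
  mrc <- Biostrings::reverseComplement(msubj)

  # lossless prefilter: a mate passing the identity threshold (<= 2% of
  # its length in mismatches) must share one exact 20-mer with a member
  # or its reverse complement
  k <- 20L
  cand <- prefilter_candidates(reads, c(as.character(msubj), as.character(mrc)), k)
  if (!length(cand)) { res$unmatched_pairs <- n; return(res) }

  m1 <- reads$mate1[cand]; m2 <- reads$mate2[cand]
  m1rc <- dna_revcomp(m1); m2rc <- dna_revcomp(m2)
  raw1 <- lapply(m1, charToRaw); raw2 <- lapply(m2, charToRaw)
  raw1rc <- lapply(m1rc, charToRaw); raw2rc <- lapply(m2rc, charToRaw)

  # per-member anchor index: exact k-mer -> 1-based member positions
  midx <- lapply(members$sequence, member_kmer_index, k = k)
  mraw <- lapply(members$sequence, charToRaw)

  for (ci in seq_along(cand)) {
    w1 <- nchar(m1[ci]); w2 <- nchar(m2[ci])
    mm1 <- floor(w1 * (1 - min_identity / 100) + 1e-9)
    mm2 <- floor(w2 * (1 - min_identity / 100) + 1e-9)
    supported <- character(0); support_mis <- numeric(0)
    for (mi in seq_len(nrow(members))) {
      mlen <- length(mraw[[mi]])
      a1   <- anchored_starts(m1[ci],   raw1[[ci]],   midx[[mi]], mraw[[mi]], k, mm1)
      a1rc <- anchored_starts(m1rc[ci], raw1rc[[ci]], midx[[mi]], mraw[[mi]], k, mm1)
      a2   <- anchored_starts(m2[ci],   raw2[[ci]],   midx[[mi]], mraw[[mi]], k, mm2)
      a2rc <- anchored_starts(m2rc[ci], raw2rc[[ci]], midx[[mi]], mraw[[mi]], k, mm2)
      best <- Inf
      # two inward-facing layouts: mate1 fwd + mate2 rc, or mate2 fwd + mate1 rc
      for (layout in 1:2) {
        if (layout == 1L) { af <- a1; ar <- a2rc; wf <- w1; wr <- w2 }
        else              { af <- a2; ar <- a1rc; wf <- w2; wr <- w1 }
        if (!nrow(af) || !nrow(ar)) next
        for (fi in seq_len(nrow(af))) for (rj in seq_len(nrow(ar))) {
          s <- af[fi, 1L]; t <- ar[rj, 1L]
          if (t < s) next
          insert <- t + wr - s
          if (insert > max_insert || insert < max(wf, wr)) next
          # footprint [s, t + wr - 1] must reach min_flank_cov into both flanks
          fu <- members$flank_up[mi]; fd <- members$flank_down[mi]
          cov_up <- max(0L, min(fu, t + wr - 1L) - s + 1L)
          cov_dn <- max(0L, min(t + wr - 1L, mlen) - max(s, mlen - fd + 1L) + 1L)
          if (cov_up < min_flank_cov || cov_dn < min_flank_cov) next
          tot <- af[fi, 2L] + ar[rj, 2L]
          if (tot < best) best <- tot
        }
      }
      if (is.finite(best)) {
        supported <- c(supported, members$label[mi])
        support_mis <- c(support_mis, best)
      }
    }
    if (!length(supported)) next
    cls <- members$class[match(supported, members$label)]
    best_orig <- suppressWarnings(min(support_mis[cls == "original"]))
    best_rec <- suppressWarnings(min(support_mis[cls == "recombinant"]))
    if (is.finite(best_orig) && is.finite(best_rec) && best_orig == best_rec) {
      # equal best support for both conformation classes: uninformative
      res$ambiguous_pairs <- res$ambiguous_pairs + 1L
    } else if (best_orig < best_rec) {
      in_cls <- cls == "original"
      best_lab <- supported[in_cls][which.min(support_mis[in_cls])]
      res$per_member[best_lab] <- res$per_member[best_lab] + 1L
      res$master_pairs <- res$master_pairs + 1L
    } else {
      in_cls <- cls == "recombinant"
      best_lab <- supported[in_cls][which.min(support_mis[in_cls])]
      res$per_member[best_lab] <- res$per_member[best_lab] + 1L
      res$alternative_pairs <- res$alternative_pairs + 1L
    }
  }
  res$unmatched_pairs <- n - res$master_pairs - res$alternative_pairs -
    res$ambiguous_pairs
  res
}

# exact k-mer -> 1-based positions within one member sequence
member_kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list())
  words <- substring(seq, 1:(n - k + 1L), k:n)
  split(seq_len(n - k + 1L), words)
}

# End-to-end placements of a mate on a member: anchor with exact k-mers
# at mm+1 evenly spaced offsets (pigeonhole: any placement with <= mm
# mismatches has a clean anchor), then verify the full-length mismatch
# count by byte comparison.  Returns matrix (start, mismatches).
anchored_starts <- function(mate, mate_raw, idx, member_raw, k, mm) {
  w <- length(mate_raw)
  mlen <- length(member_raw)
  nblocks <- mm + 1L
  block <- w %/% nblocks
  offs <- if (block >= k) (0:mm) * block + 1L else
    unique(pmin(seq(1L, w - k + 1L, by = max(1L, k %/% 2L)), w - k + 1L))
  starts <- integer(0)
  for (o in offs) {
    hit <- idx[[substring(mate, o, o + k - 1L)]]
    if (!is.null(hit)) starts <- c(starts, hit - o + 1L)
  }
  starts <- unique(starts)
  starts <- starts[starts >= 1L & starts + w - 1L <= mlen]
  if (!length(starts)) return(matrix(integer(0), ncol = 2L))
  out <- matrix(integer(0), ncol = 2L)
  for (s in starts) {
    mis <- sum(member_raw[s:(s + w - 1L)] != mate_raw)
    if (mis <= mm) out <- rbind(out, c(s, mis))
  }
  out
}

# indices of read pairs sharing an exact k-mer with any panel sequence
prefilter_candidates <- function(reads, panel_seqs, k) {
  n <- nrow(reads)
  if (n == 0L) return(integer(0))
  if (any(nchar(reads$mate1) < k) || any(nchar(reads$mate2) < k))
    return(seq_len(n))
  words <- unique(unlist(lapply(panel_seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  })))
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (!length(words)) return(integer(0))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(words))
  h1 <- Biostrings::vwhichPDict(pd, Biostrings::DNAStringSet(reads$mate1))
  h2 <- Biostrings::vwhichPDict(pd, Biostrings::DNAStringSet(reads$mate2))
  which(lengths(h1) > 0L | lengths(h2) > 0L)
}

#' @export
print.support_counts <- function(x, ...) {
  cat(sprintf("<support_counts '%s': master=%d alternative=%d ambiguous=%d unmatched=%d>\n",
              x$pair_id, x$master_pairs, x$alternative_pairs,
              x$ambiguous_pairs, x$unmatched_pairs))
  invisible(x)
}

#' Per-repeat recombination rate
#'
#' The percentage of junction-informative read pairs supporting any
#' recombinant panel member: `100 * alternative / (master + alternative)`,
#' reported to two decimals.
#'
#' @param counts A `support_counts` object, or a list with
#'   `master_pairs` and `alternative_pairs`.
#' @return Rate in percent, rounded to 2 decimals.
#' @export
#' @examples
#' recombination_rate(list(master_pairs = 30, alternative_pairs = 14))  # 31.82
recombination_rate <- function(counts) {
  m <- counts$master_pairs; a <- counts$alternative_pairs
  if (m + a <= 0)
    stop("undefined recombination rate: no informative read pairs", call. = FALSE)
  round(100 * a / (m + a), 2)
}
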