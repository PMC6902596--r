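# Dispersed repeat discovery on circular genomes.
#
# Seed-and-extend: exact seed words (default 11 bp, the classic blastn
# word size) are hashed over the circular sequence; seed pairs are
# clustered by diagonal (direct) or anti-diagonal (inverted) and each
# cluster is extended ungapped under +1/-2 scoring with Ruzzo-Tompa
# maximal-segment trimming.  Circularity is handled by working on the
# tripled sequence and deduplicating hits modulo the genome length.

# 0-based start positions of each distinct word of the circular sequence
kmer_index <- function(s, L, k) {
  s2 <- paste0(s, substring(s, 1L, k - 1L))
  words <- substring(s2, 1:L, k:(L + k - 1L))
  keep <- !grepl("N", words, fixed = TRUE)
  split(which(keep) - 1L, words[keep])
}

# cluster sorted positions: break where the gap exceeds `gap`
cluster_breaks <- function(p, gap) {
  if (length(p) <= 1L) return(rep.int(1L, length(p)))
  cumsum(c(1L, diff(p) > gap))
}

# Extend one diagonal candidate.  a3/b3 are tripled strings; positions
# compared are a3[p + 1] vs b3[p + off + 1] (0-based p).  Returns
# segments as 0-based a-start + length + matches.
extend_diagonal <- function(a3, b3, off, p_min, p_max, k, L, min_len) {
  W <- 150L
  repeat {
    lo <- max(0L, p_min - W)
    hi <- min(p_max + k + W, 2L * L, nchar(a3) - max(0L, off), nchar(b3) - max(0L, -off))
    width <- hi - lo
    if (width < min_len) return(NULL)
    a <- substring(a3, lo + 1L, hi)
    b <- substring(b3, lo + off + 1L, hi + off)
    m <- match_vector(a, b)
    segs <- max_scoring_segments(m)
    if (nrow(segs) == 0L) return(NULL)
    touches <- (any(segs[, "start"] == 1L) && lo > 0L) ||
      (any(segs[, "end"] == width) && hi < min(2L * L, nchar(a3) - max(0L, off)))
    if (!touches || W >= L) {
      return(cbind(a_start = lo + segs[, "start"] - 1L,
                   len = segs[, "end"] - segs[, "start"] + 1L,
                   matches = segs[, "matches"]))
    }
    W <- W * 2L
  }
}

#' Find dispersed repeat pairs on a circular genome
#'
#' Detects direct and inverted repeat pairs meeting the classical
#' thresholds for recombinogenic repeats: aligned length above `min_len`
#' and identity above `min_identity` percent.  Self-hits and mirror
#' duplicates are removed and hits contained in a larger pair are
#' collapsed to the maximal-scoring pair.
#'
#' @param genome An [annotated_genome()].
#' @param min_len Minimum aligned length in bp (default 50).
#' @param min_identity Minimum identity in percent (default 85).
#' @param directions Subset of `c("direct", "inverted")`.
#' @param seed_len Exact seed word length (default 11).
#' @param max_word_hits Words occurring more often than this are skipped
#'   as low-complexity (default 8).
#' @return A data.frame of class `repeat_pairs`: one row per pair with
#'   0-based half-open copy intervals (`copy1_start`..`copy2_end`),
#'   `direction`, `identity_pct`, `aligned_length` and the two aligned
#'   copy sequences (`aln1`, `aln2`; identity is recomputable from them).
#'   Attribute `genome_length` carries the circle size.
#' @export
find_repeat_pairs <- function(genome, min_len = 50, min_identity = 85,
                              directions = c("direct", "inverted"),
                              seed_len = 11L, max_word_hits = 8L) {
  directions <- match.arg(directions, several.ok = TRUE)
  s <- genome$sequence
  assert_dna(s, "genome sequence")
  L <- genome$length
  if (L < 2L * min_len)
    stop("genome shorter than twice min_len", call. = FALSE)
  k <- as.integer(seed_len)
  s3 <- strrep(s, 3L)
  rows <- list()
  add_row <- function(c1, c2, direction, matches, len, a_sub, b_sub) {
    rows[[length(rows) + 1L]] <<- data.frame(
      copy1_start = c1$start, copy1_end = c1$end,
      copy2_start = c2$start, copy2_end = c2$end,
      direction = direction,
      identity_pct = 100 * matches / len,
      aligned_length = len, score = MATCH_SCORE * matches +
        MISMATCH_SCORE * (len - matches),
      aln1 = a_sub, aln2 = b_sub, stringsAsFactors = FALSE)
  }

  idx <- kmer_index(s, L, k)
  idx <- idx[lengths(idx) <= max_word_hits | lengths(idx) <= 1L]

  if ("direct" %in% directions) {
    # seed pairs (i < j), normalised to diagonal d in [1, floor(L/2)]
    seed_p <- integer(0); seed_d <- integer(0)
    for (pos in idx[lengths(idx) >= 2L]) {
      cmb <- utils::combn(pos, 2L)
      i <- cmb[1L, ]; j <- cmb[2L, ]
      d <- j - i
      flip <- d > L - d
      p <- ifelse(flip, j, i)
      d <- pmin(d, L - d)
      keep <- d > 0L
      seed_p <- c(seed_p, p[keep]); seed_d <- c(seed_d, d[keep])
    }
    if (length(seed_p)) {
      o <- order(seed_d, seed_p)
      seed_p <- seed_p[o]; seed_d <- seed_d[o]
      for (d in unique(seed_d)) {
        p <- seed_p[seed_d == d]
        cl <- cluster_breaks(p, 2L * k + 20L)
        for (ci in unique(cl)) {
          pc <- p[cl == ci]
          segs <- extend_diagonal(s3, s3, d, min(pc), max(pc), k, L, min_len)
          if (is.null(segs)) next
          for (r in seq_len(nrow(segs))) {
            len <- segs[r, "len"]
            if (len < min_len || len > L - d) next
            ident <- 100 * segs[r, "matches"] / len
            if (ident < min_identity - 1e-9) next
            a0 <- segs[r, "a_start"]
            c1 <- interval_from_span(a0, len, L)
            c2 <- interval_from_span(a0 + d, len, L)
            add_row(c1, c2, "direct", segs[r, "matches"], len,
                    substring(s3, a0 + 1L, a0 + len),
                    substring(s3, a0 + d + 1L, a0 + d + len))
          }
        }
      }
    }
  }

  if ("inverted" %in% directions) {
    rs <- dna_revcomp(s)
    r3 <- strrep(rs, 3L)
    ridx <- kmer_index(rs, L, k)
    ridx <- ridx[lengths(ridx) <= max_word_hits | lengths(ridx) <= 1L]
    common <- intersect(names(idx), names(ridx))
    seed_p <- integer(0); seed_o <- integer(0)
    for (w in common) {
      for (i in idx[[w]]) for (u in ridx[[w]]) {
        seed_p <- c(seed_p, i); seed_o <- c(seed_o, u - i)
      }
    }
    if (length(seed_p)) {
      o <- order(seed_o, seed_p)
      seed_p <- seed_p[o]; seed_o <- seed_o[o]
      for (off in unique(seed_o)) {
        p <- seed_p[seed_o == off]
        cl <- cluster_breaks(p, 2L * k + 20L)
        for (ci in unique(cl)) {
          pc <- p[cl == ci]
          # b index = p + off + L (shift keeps indices positive in r3)
          segs <- extend_diagonal(s3, r3, off + L, min(pc), max(pc), k, L, min_len)
          if (is.null(segs)) next
          for (r in seq_len(nrow(segs))) {
            len <- segs[r, "len"]
            if (len < min_len || len > L) next
            ident <- 100 * segs[r, "matches"] / len
            if (ident < min_identity - 1e-9) next
            a0 <- segs[r, "a_start"]
            u0 <- (a0 + off) %% L            # 0-based start on revcomp strand
            c1 <- interval_from_span(a0, len, L)
            c2 <- interval_from_span(L - u0 - len, len, L)
            if (c1$start == c2$start && c1$end == c2$end) next  # self palindrome
            add_row(c1, c2, "inverted", segs[r, "matches"], len,
                    substring(s3, a0 + 1L, a0 + len),
                    substring(r3, a0 + off + L + 1L, a0 + off + L + len))
          }
        }
      }
    }
  }

  if (length(rows) == 0L) return(empty_repeat_pairs(genome))
  df <- do.call(rbind, rows)
  df <- canonicalize_pairs(df, L)
  df <- collapse_contained(df, L)
  df <- df[order(df$copy1_start, df$copy2_start, df$direction), , drop = FALSE]
  df$id <- sprintf("rp%03d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df <- df[, c("id", "copy1_start", "copy1_end", "copy2_start", "copy2_end",
               "direction", "identity_pct", "aligned_length", "score",
               "aln1", "aln2")]
  structure(df, class = c("repeat_pairs", "data.frame"),
            genome_length = L, genome_id = genome$id)
}

empty_repeat_pairs <- function(genome) {
  structure(data.frame(id = character(0), copy1_start = integer(0),
                       copy1_end = integer(0), copy2_start = integer(0),
                       copy2_end = integer(0), direction = character(0),
                       identity_pct = numeric(0), aligned_length = integer(0),
                       score = numeric(0), aln1 = character(0),
                       aln2 = character(0), stringsAsFactors = FALSE),
            class = c("repeat_pairs", "data.frame"),
            genome_length = genome$length, genome_id = genome$id)
}

# order copies by start; swap aligned strings accordingly; drop exact dups
canonicalize_pairs <- function(df, L) {
  swap <- df$copy2_start < df$copy1_start |
    (df$copy2_start == df$copy1_start & df$copy2_end < df$copy1_end)
  if (any(swap)) {
    tmp <- df[swap, c("copy1_start", "copy1_end", "aln1")]
    df[swap, c("copy1_start", "copy1_end")] <- df[swap, c("copy2_start", "copy2_end")]
    df[swap, "aln1"] <- df[swap, "aln2"]
    df[swap, c("copy2_start", "copy2_end")] <- tmp[, c("copy1_start", "copy1_end")]
    df[swap, "aln2"] <- tmp$aln1
  }
  # identical copy intervals are self hits
  df <- df[!(df$copy1_start == df$copy2_start & df$copy1_end == df$copy2_end), ,
           drop = FALSE]
  key <- paste(df$copy1_start, df$copy1_end, df$copy2_start, df$copy2_end,
               df$direction)
  df[!duplicated(key), , drop = FALSE]
}

collapse_contained <- function(df, L) {
  n <- nrow(df)
  if (n <= 1L) return(df)
  ivs1 <- lapply(seq_len(n), function(i) circ_interval(df$copy1_start[i], df$copy1_end[i], L))
  ivs2 <- lapply(seq_len(n), function(i) circ_interval(df$copy2_start[i], df$copy2_end[i], L))
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || drop[j]) next
    if (df$direction[i] != df$direction[j]) next
    # j absorbs i when i's copies both lie inside j's and j scores at
    # least as well (earlier row wins ties)
    better <- df$score[j] > df$score[i] ||
      (df$score[j] == df$score[i] && j < i)
    if (!better) next
    contained <- (interval_contains(ivs1[[j]], ivs1[[i]]) &&
                    interval_contains(ivs2[[j]], ivs2[[i]])) ||
      (interval_contains(ivs1[[j]], ivs2[[i]]) &&
         interval_contains(ivs2[[j]], ivs1[[i]]))
    if (contained) drop[i] <- TRUE
  }
  df[!drop, , drop = FALSE]
}

#' Select repeats assayable for recombination by read pairs
#'
#' Keeps pairs whose aligned length lies in `[min_len, max_len]`
#' (inclusive) and whose copies do not overlap on the circle, i.e. the
#' repeats whose junctions a short-insert paired-end library can
#' interrogate.  `max_len` reflects the insert-size design: with 2x150 bp
#' reads and ~350 bp inserts, both repeat ends can be anchored in flanking
#' sequence only for repeats up to about 250 bp.
#'
#' @param pairs A `repeat_pairs` data.frame from [find_repeat_pairs()].
#' @param min_len,max_len Inclusive aligned-length bounds (default 50-250).
#' @param min_copy_gap Minimum bp between the copies on both arcs
#'   (default 1, i.e. copies must be disjoint and non-adjacent).
#' @return The filtered `repeat_pairs` data.frame, stably ordered by
#'   `copy1_start`.
#' @export
select_assayable_repeats <- function(pairs, min_len = 50, max_len = 250,
                                     min_copy_gap = 1) {
  if (nrow(pairs) == 0L) return(pairs)
  L <- attr(pairs, "genome_length")
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    len <- pairs$aligned_length[i]
    if (len < min_len || len > max_len) next
    c1 <- circ_interval(pairs$copy1_start[i], pairs$copy1_end[i], L)
    c2 <- circ_interval(pairs$copy2_start[i], pairs$copy2_end[i], L)
    if (interval_overlap(c1, c2) > 0L) next
    gapA <- (c2$start - c1$end) %% L
    gapB <- (c1$start - c2$end) %% L
    if (min(gapA, gapB) < min_copy_gap) next
    keep[i] <- TRUE
  }
  out <- pairs[keep, , drop = FALSE]
  out <- out[order(out$copy1_start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(pairs),
            genome_length = L, genome_id = attr(pairs, "genome_id"))
}

#' Write repeat pairs as TSV
#'
#' Coordinates are written 1-based inclusive; for a copy wrapping the
#' origin the end exceeds the genome length (continue counting past the
#' origin).
#'
#' @param pairs A `repeat_pairs` data.frame.
#' @param path Output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_repeats_tsv <- function(pairs, path) {
  L <- attr(pairs, "genome_length")
  unwrap_end <- function(s, e) ifelse(e > s, e, e + L)
  out <- data.frame(
    id = pairs$id,
    copy1_start = pairs$copy1_start + 1L,
    copy1_end = unwrap_end(pairs$copy1_start, pairs$copy1_end),
    copy2_start = pairs$copy2_start + 1L,
    copy2_end = unwrap_end(pairs$copy2_start, pairs$copy2_end),
    direction = pairs$direction,
    identity_pct = round(pairs$identity_pct, 2),
    aligned_length = pairs$aligned_length,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

# circ_interval accessors for a pair row
pair_copy <- function(pairs, i, which = c("copy1", "copy2")) {
  which <- match.arg(which)
  L <- attr(pairs, "genome_length")
  circ_interval(pairs[[paste0(which, "_start")]][i],
                pairs[[paste0(which, "_end")]][i], L)
}
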