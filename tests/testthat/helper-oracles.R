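# Independent brute-force oracles used to cross-check the package
# implementations.  These deliberately avoid the package's internal
# code paths: interval arithmetic by base enumeration, repeat discovery
# by exhaustive diagonal scanning, inversion distance by a standalone
# breadth-first search.

# bases of the circle covered by a (start0, end0, L) interval, by brute
# enumeration of all positions
oracle_interval_positions <- function(start, end, L) {
  span <- (end - start) %% L
  if (span == 0) span <- L
  (seq(start, length.out = span) %% L)
}

oracle_overlap <- function(a, b, L) {
  length(intersect(oracle_interval_positions(a[1], a[2], L),
                   oracle_interval_positions(b[1], b[2], L)))
}

# --- exhaustive repeat scan --------------------------------------------

# all maximal +1/-2 scoring segments of a logical vector, by iterated
# best-segment extraction over match-run endpoints
oracle_segments <- function(m) {
  r <- rle(m)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sc <- ifelse(r$values, 1, -2) * r$lengths
  mb <- which(r$values)
  if (!length(mb)) return(NULL)
  cum <- cumsum(c(0, sc))
  recurse <- function(blocks) {
    blocks <- blocks[r$values[blocks]]
    if (!length(blocks)) return(NULL)
    # on score ties the canonical maximal set keeps the later segment
    # separate, so the tie-break is: highest score, then rightmost
    # start, then shortest extent
    best <- NULL; best_score <- 0
    for (i in blocks) for (j in blocks[blocks >= i]) {
      s <- cum[j + 1L] - cum[i]
      if (s > best_score ||
          (s == best_score && !is.null(best) &&
           (i > best[1] || (i == best[1] && j < best[2])))) {
        best <- c(i, j); best_score <- s
      }
    }
    if (is.null(best)) return(NULL)
    left <- blocks[blocks < best[1]]
    right <- blocks[blocks > best[2]]
    rbind(recurse(left),
          c(start = starts[best[1]], end = ends[best[2]], score = best_score,
            matches = sum(r$lengths[best[1]:best[2]][r$values[best[1]:best[2]]])),
          recurse(right))
  }
  recurse(mb)
}

# exhaustive dispersed-repeat scan of a circular genome: every diagonal
# (direct) and anti-diagonal (inverted) is tested; a cheap windowed
# screen (50-bp window with >= 35 matches, which any >=50 bp / >=85 %
# segment must contain) selects diagonals for full segment extraction
oracle_repeat_scan <- function(seq, min_len = 50, min_identity = 85) {
  L <- nchar(seq)
  s2 <- strrep(seq, 2)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  r2 <- strrep(rc, 2)
  raw_s <- charToRaw(substring(s2, 1, 2 * L))
  raw_r <- charToRaw(substring(r2, 1, 2 * L))
  found <- list()
  screen_hits <- function(m) {
    if (length(m) < min_len) return(NULL)
    cs <- cumsum(m)
    wm <- cs[min_len:length(m)] - c(0, cs)[1:(length(m) - min_len + 1)]
    which(wm >= 35)
  }
  harvest <- function(m, register) {
    hits <- screen_hits(m)
    if (!length(hits)) return()
    lo <- max(1L, min(hits) - 200L); hi <- min(length(m), max(hits) + min_len + 200L)
    segs <- oracle_segments(m[lo:hi])
    if (is.null(segs)) return()
    for (k in seq_len(nrow(segs))) {
      len <- segs[k, "end"] - segs[k, "start"] + 1L
      if (len < min_len) next
      if (100 * segs[k, "matches"] / len < min_identity - 1e-9) next
      register(lo + segs[k, "start"] - 1L, len, segs[k, "matches"])
    }
  }
  for (d in 1:(L - 1)) {
    m <- raw_s[1:L] == raw_s[(1 + d):(L + d)]
    harvest(m, function(i1, len, matches) {
      c1 <- (i1 - 1) %% L; c2 <- (i1 - 1 + d) %% L
      found[[length(found) + 1L]] <<- data.frame(
        c1 = min(c1, c2), c2 = max(c1, c2), len = len, matches = matches,
        direction = "direct")
    })
  }
  for (o in 0:(L - 1)) {
    m <- raw_s[1:L] == raw_r[(1 + o):(L + o)]
    harvest(m, function(i1, len, matches) {
      a <- (i1 - 1) %% L
      u <- (i1 - 1 + o) %% L
      b <- (L - u - len) %% L
      if (a == b) return()
      found[[length(found) + 1L]] <<- data.frame(
        c1 = min(a, b), c2 = max(a, b), len = len, matches = matches,
        direction = "inverted")
    })
  }
  if (!length(found)) {
    return(data.frame(c1 = integer(0), c2 = integer(0), len = integer(0),
                      matches = integer(0), direction = character(0)))
  }
  df <- do.call(rbind, found)
  df <- unique(df)
  df[order(df$c1, df$c2, df$direction), , drop = FALSE]
}

# repeat_pairs data.frame -> the oracle's comparable form
pairs_to_oracle_form <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(c1 = integer(0), c2 = integer(0), len = integer(0),
                      matches = integer(0), direction = character(0)))
  }
  df <- data.frame(c1 = pairs$copy1_start, c2 = pairs$copy2_start,
                   len = pairs$aligned_length,
                   matches = as.integer(round(pairs$identity_pct *
                                                pairs$aligned_length / 100)),
                   direction = pairs$direction)
  rownames(df) <- NULL
  df[order(df$c1, df$c2, df$direction), , drop = FALSE]
}

# --- inversion-distance BFS oracle -------------------------------------

# canonical representation of a signed circular order, own implementation
oracle_canon <- function(labs, sgn) {
  n <- length(labs)
  best <- NULL
  for (refl in 0:1) {
    ll <- labs; ss <- sgn
    if (refl) { ll <- rev(ll); ss <- -rev(ss) }
    for (r in 0:(n - 1)) {
      idx <- ((seq_len(n) - 1 + r) %% n) + 1
      key <- paste(ss[idx] * match(ll[idx], sort(labs)), collapse = ",")
      if (is.null(best) || key < best) best <- key
    }
  }
  best
}

oracle_inversion_distance <- function(labs1, sgn1, labs2, sgn2, cap = 4L) {
  target <- oracle_canon(labs2, sgn2)
  if (oracle_canon(labs1, sgn1) == target) return(0L)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  frontier <- list(list(l = labs1, s = sgn1))
  n <- length(labs1)
  for (depth in seq_len(cap)) {
    nxt <- list()
    for (st in frontier) {
      for (i in 1:n) for (j in i:n) {
        l2 <- st$l; s2v <- st$s
        l2[i:j] <- rev(l2[i:j]); s2v[i:j] <- -rev(s2v[i:j])
        key <- oracle_canon(l2, s2v)
        if (key == target) return(depth)
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- list(l = l2, s = s2v)
        }
      }
    }
    frontier <- nxt
  }
  NA_integer_
}

# --- misc helpers -------------------------------------------------------

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant an exact or mutated copy of a segment at a target position,
# independent of the package generator (string surgery only)
plant_copy <- function(seq, src_start, len, tgt_start, n_mut = 0, inverted = FALSE,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  copy <- substring(seq, src_start, src_start + len - 1)
  if (n_mut > 0) {
    ch <- strsplit(copy, "")[[1]]
    at <- sample.int(len, n_mut)
    for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    copy <- paste(ch, collapse = "")
  }
  if (inverted)
    copy <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(copy)))
  paste0(substring(seq, 1, tgt_start - 1), copy,
         substring(seq, tgt_start + len, nchar(seq)))
}
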