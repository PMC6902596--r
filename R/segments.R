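# Maximal scoring segment machinery shared by the repeat finder.
#
# Scores follow megablast-like ungapped scoring: match +1, mismatch -2
# (an N never matches).  All maximal scoring segments of the +1/-2
# series are found with the Ruzzo-Tompa linear-time algorithm, run over
# run-length blocks so the work is proportional to the number of
# match/mismatch runs, not bases.

MATCH_SCORE <- 1
MISMATCH_SCORE <- -2

# match vector of two equal-length chunks (raw comparison; N matches nothing)
match_vector <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  (ra == rb) & (ra != charToRaw("N")[1L])
}

# All maximal scoring segments of a logical match vector under +1/-2.
# Returns a matrix with columns start, end (1-based inclusive), score,
# matches; zero rows when no positive segment exists.
max_scoring_segments <- function(m) {
  if (length(m) == 0L || !any(m)) {
    return(matrix(numeric(0), ncol = 4L,
                  dimnames = list(NULL, c("start", "end", "score", "matches"))))
  }
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sc <- ifelse(r$values, MATCH_SCORE, MISMATCH_SCORE) * r$lengths
  # only match blocks can begin/end a maximal segment
  n <- length(sc)
  cum <- cumsum(c(0, sc))  # cum[i+1] = score of blocks 1..i
  # Ruzzo-Tompa over blocks: candidate segments (i, j) with L = cum
  # before block i and R = cum through block j, kept on vector stacks
  si <- integer(n); sj <- integer(n); sL <- numeric(n); sR <- numeric(n)
  top <- 0L
  for (k in seq_len(n)) {
    if (!r$values[k]) next
    ci <- k; cj <- k; cL <- cum[k]; cR <- cum[k + 1L]
    repeat {
      jidx <- top
      while (jidx >= 1L && sL[jidx] >= cL) jidx <- jidx - 1L
      if (jidx == 0L || sR[jidx] >= cR) {
        top <- top + 1L
        si[top] <- ci; sj[top] <- cj; sL[top] <- cL; sR[top] <- cR
        break
      }
      # merge: stacked segment jidx extends to the current end
      ci <- si[jidx]; cL <- sL[jidx]; cj <- cj; cR <- cR
      top <- jidx - 1L
    }
  }
  if (top == 0L) {
    return(matrix(numeric(0), ncol = 4L,
                  dimnames = list(NULL, c("start", "end", "score", "matches"))))
  }
  keep <- seq_len(top)
  mcum <- cumsum(ifelse(r$values, r$lengths, 0L))
  nmatch <- mcum[sj[keep]] - c(0L, mcum)[si[keep]]
  out <- cbind(start = starts[si[keep]], end = ends[sj[keep]],
               score = sR[keep] - sL[keep], matches = nmatch)
  out[out[, "score"] > 0, , drop = FALSE]
}
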