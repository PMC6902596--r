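# Genome partition into exon/intron/spacer and decomposition of the
# spacer fraction into ORF, dispersed-repeat and microsatellite content.
# Interval algebra is done with IRanges on the linearised circle
# (wrapping intervals contribute their two linear segments).

features_to_iranges <- function(genome, kinds) {
  segs <- list()
  for (f in genome$features) {
    if (!f$kind %in% kinds) next
    m <- interval_segments(f$interval)
    segs[[length(segs) + 1L]] <- m
  }
  if (!length(segs)) return(IRanges::IRanges())
  m <- do.call(rbind, segs)
  IRanges::IRanges(start = m[, 1L], end = m[, 2L])
}

# exonic track: explicit exons, whole tRNA/rRNA features, and genes with
# no exon/intron children (their whole interval is exonic)
exon_iranges <- function(genome) {
  ft <- features_table(genome)
  has_kids <- unique(stats::na.omit(ft$parent[ft$kind %in% c("exon", "intron")]))
  segs <- list()
  for (f in genome$features) {
    take <- f$kind %in% c("exon", "tRNA", "rRNA") ||
      (f$kind == "gene" && !f$id %in% has_kids)
    if (!take) next
    segs[[length(segs) + 1L]] <- interval_segments(f$interval)
  }
  if (!length(segs)) return(IRanges::IRanges())
  m <- do.call(rbind, segs)
  IRanges::reduce(IRanges::IRanges(start = m[, 1L], end = m[, 2L]))
}

#' Partition a genome into exonic, intronic and spacer fractions
#'
#' Exon = union of exon intervals of genes, tRNAs and rRNAs; intron =
#' union of intron intervals minus exons; spacer = the complement.
#' Overlaps are resolved by the precedence exon > intron > spacer, and
#' overlapping annotations are merged (union semantics) before summing,
#' so the three fractions always add up to the genome length exactly.
#'
#' @param genome An [annotated_genome()].
#' @return A list of class `composition_profile` with bp and percent
#'   fields (`exon_bp`, `intron_bp`, `spacer_bp`, ...).
#' @export
partition_genome <- function(genome) {
  L <- genome$length
  ex <- exon_iranges(genome)
  intr <- IRanges::reduce(features_to_iranges(genome, "intron"))
  intr <- IRanges::setdiff(intr, ex)
  exon_bp <- sum(IRanges::width(ex))
  intron_bp <- sum(IRanges::width(intr))
  spacer_bp <- L - exon_bp - intron_bp
  structure(list(genome_id = genome$id, total_bp = L,
                 exon_bp = exon_bp, intron_bp = intron_bp, spacer_bp = spacer_bp,
                 exon_pct = 100 * exon_bp / L,
                 intron_pct = 100 * intron_bp / L,
                 spacer_pct = 100 * spacer_bp / L,
                 spacer_orf_bp = NA_real_, spacer_repeat_bp = NA_real_,
                 spacer_ssr_bp = NA_real_),
            class = "composition_profile")
}

spacer_iranges <- function(genome) {
  L <- genome$length
  genic <- IRanges::reduce(IRanges::union(exon_iranges(genome),
                                          features_to_iranges(genome, "intron")))
  IRanges::setdiff(IRanges::IRanges(1L, L), genic)
}

#' Find open reading frames in a sequence
#'
#' Start(ATG)-to-stop frames on both strands, at least `min_codons`
#' codons long (stop codon included).
#'
#' @param seq DNA string.
#' @param min_codons Minimum ORF length in codons (default 100).
#' @return Data.frame with 1-based `start`, `end` (on the forward
#'   strand), `strand`, `codons`.
#' @export
find_orfs <- function(seq, min_codons = 100) {
  n <- nchar(seq)
  out <- list()
  scan_strand <- function(s, strand) {
    for (frame in 0:2) {
      if (frame + 1L > n - 2L) next
      starts <- seq.int(frame + 1L, n - 2L, by = 3L)
      if (!length(starts)) next
      codons <- substring(s, starts, starts + 2L)
      is_start <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      open_at <- NA_integer_
      for (ci in seq_along(codons)) {
        if (is.na(open_at) && is_start[ci]) open_at <- ci
        if (!is.na(open_at) && is_stop[ci]) {
          ncod <- ci - open_at + 1L
          if (ncod >= min_codons) {
            a <- starts[open_at]; b <- starts[ci] + 2L
            if (strand == "+") {
              out[[length(out) + 1L]] <<- data.frame(start = a, end = b,
                                                     strand = strand, codons = ncod)
            } else {
              out[[length(out) + 1L]] <<- data.frame(start = n - b + 1L,
                                                     end = n - a + 1L,
                                                     strand = strand, codons = ncod)
            }
          }
          open_at <- NA_integer_
        }
      }
    }
  }
  scan_strand(seq, "+")
  scan_strand(dna_revcomp(seq), "-")
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), codons = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

#' Find perfect microsatellites (SSRs)
#'
#' Perfect tandem repeats of 1-6 bp motifs meeting per-motif-length
#' minimum repeat counts (defaults 10, 6, 5, 5, 5, 5 for motif lengths
#' 1-6, the common microsatellite survey convention).
#'
#' @param seq DNA string.
#' @param min_counts Integer vector of length 6: minimum number of
#'   tandem motif copies for motif lengths 1..6.
#' @return Data.frame with 1-based `start`, `end`, `motif`, `n_copies`.
#' @export
find_ssrs <- function(seq, min_counts = c(10, 6, 5, 5, 5, 5)) {
  stopifnot(length(min_counts) == 6L)
  out <- list()
  for (k in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, min_counts[k] - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    for (ii in seq_along(m)) {
      motif <- substring(seq, m[ii], m[ii] + k - 1L)
      # skip motifs that are themselves tandem repeats of a shorter unit
      if (k > 1L && is_periodic(motif)) next
      ncop <- len[ii] %/% k
      out[[length(out) + 1L]] <- data.frame(start = as.integer(m[ii]),
                                            end = as.integer(m[ii] + ncop * k - 1L),
                                            motif = motif, n_copies = ncop)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), n_copies = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

is_periodic <- function(motif) {
  k <- nchar(motif)
  for (p in seq_len(k - 1L)) {
    if (k %% p == 0L && motif == strrep(substring(motif, 1L, p), k %/% p)) return(TRUE)
  }
  FALSE
}

#' Full spacer composition profile
#'
#' Extends [partition_genome()] with the ORF, dispersed-repeat and SSR
#' content of the intergenic spacers.  Each category is reported as
#' merged base coverage clipped to the spacer track, so there is no
#' double counting within a category.
#'
#' @param genome An [annotated_genome()].
#' @param repeats Optional `repeat_pairs` data.frame from
#'   [find_repeat_pairs()]; repeat content is the spacer bases covered by
#'   the repeat copies.
#' @param orf_min_codons Minimum ORF length in codons (default 100).
#' @param ssr_min_counts Per-motif-length minimum tandem copy counts.
#' @return A `composition_profile` with the spacer sub-categories filled
#'   in (`spacer_orf_bp`, `spacer_repeat_bp`, `spacer_ssr_bp` and their
#'   percents of spacer length).
#' @export
profile_spacers <- function(genome, repeats = NULL, orf_min_codons = 100,
                            ssr_min_counts = c(10, 6, 5, 5, 5, 5)) {
  prof <- partition_genome(genome)
  sp <- spacer_iranges(genome)
  orf_cov <- IRanges::IRanges(); ssr_cov <- IRanges::IRanges()
  for (ii in seq_along(sp)) {
    a <- IRanges::start(sp)[ii]; b <- IRanges::end(sp)[ii]
    sub <- substring(genome$sequence, a, b)
    orfs <- find_orfs(sub, min_codons = orf_min_codons)
    if (nrow(orfs))
      orf_cov <- c(orf_cov, IRanges::IRanges(orfs$start + a - 1L, orfs$end + a - 1L))
    ssrs <- find_ssrs(sub, min_counts = ssr_min_counts)
    if (nrow(ssrs))
      ssr_cov <- c(ssr_cov, IRanges::IRanges(ssrs$start + a - 1L, ssrs$end + a - 1L))
  }
  rep_cov <- IRanges::IRanges()
  if (!is.null(repeats) && nrow(repeats) > 0L) {
    L <- attr(repeats, "genome_length")
    segs <- list()
    for (i in seq_len(nrow(repeats))) {
      segs[[length(segs) + 1L]] <- interval_segments(pair_copy(repeats, i, "copy1"))
      segs[[length(segs) + 1L]] <- interval_segments(pair_copy(repeats, i, "copy2"))
    }
    m <- do.call(rbind, segs)
    rep_cov <- IRanges::IRanges(start = m[, 1L], end = m[, 2L])
  }
  clip <- function(x) sum(IRanges::width(IRanges::intersect(IRanges::reduce(x), sp)))
  prof$spacer_orf_bp <- clip(orf_cov)
  prof$spacer_repeat_bp <- clip(rep_cov)
  prof$spacer_ssr_bp <- clip(ssr_cov)
  sb <- prof$spacer_bp
  prof$spacer_orf_pct <- if (sb > 0) 100 * prof$spacer_orf_bp / sb else NA_real_
  prof$spacer_repeat_pct <- if (sb > 0) 100 * prof$spacer_repeat_bp / sb else NA_real_
  prof$spacer_ssr_pct <- if (sb > 0) 100 * prof$spacer_ssr_bp / sb else NA_real_
  prof
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile '%s': %d bp = exon %d (%.1f%%) + intron %d (%.1f%%) + spacer %d (%.1f%%)>\n",
              x$genome_id, x$total_bp, x$exon_bp, x$exon_pct, x$intron_bp,
              x$intron_pct, x$spacer_bp, x$spacer_pct))
  if (!is.na(x$spacer_orf_bp))
    cat(sprintf("  spacer content: ORF %d bp, repeats %d bp, SSR %d bp\n",
                x$spacer_orf_bp, x$spacer_repeat_bp, x$spacer_ssr_bp))
  invisible(x)
}

#' Write composition profiles as TSV
#'
#' @param profiles List of `composition_profile` objects.
#' @param path Output path.
#' @param header Optional provenance comment lines.
#' @return Invisibly, the written data.frame.
#' @export
write_composition_tsv <- function(profiles, path, header = NULL) {
  rows <- lapply(profiles, function(p) {
    data.frame(genome_id = p$genome_id, total_bp = p$total_bp,
               exon_bp = p$exon_bp, intron_bp = p$intron_bp,
               spacer_bp = p$spacer_bp,
               exon_pct = round(p$exon_pct, 2), intron_pct = round(p$intron_pct, 2),
               spacer_pct = round(p$spacer_pct, 2),
               spacer_orf_bp = p$spacer_orf_bp,
               spacer_repeat_bp = p$spacer_repeat_bp,
               spacer_ssr_bp = p$spacer_ssr_bp,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
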