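FEATURE_KINDS <- c("gene", "exon", "intron", "tRNA", "rRNA", "ORF", "repeat", "SSR")

#' Genome features
#'
#' A typed feature on a circular genome.  `exon` and `intron` features must
#' name their parent gene via `attributes$parent`.
#'
#' @param id Unique feature identifier.
#' @param kind One of `gene, exon, intron, tRNA, rRNA, ORF, repeat, SSR`.
#' @param interval A [circ_interval()].
#' @param strand `"+"` or `"-"`.
#' @param gene_name Gene symbol (may be empty).
#' @param attributes Named list of extra key/value strings (e.g. `parent`).
#' @return An object of class `mt_feature`.
#' @export
mt_feature <- function(id, kind, interval, strand = "+", gene_name = "",
                       attributes = list()) {
  kind <- match.arg(kind, FEATURE_KINDS)
  strand <- match.arg(strand, c("+", "-"))
  if (!inherits(interval, "circ_interval")) stop("interval must be a circ_interval")
  if (interval_span(interval) == interval$genome_length)
    stop("feature '", id, "' spans the whole circle", call. = FALSE)
  structure(list(id = as.character(id), kind = kind, gene_name = gene_name,
                 interval = interval, strand = strand,
                 attributes = attributes),
            class = "mt_feature")
}

#' Annotated circular genomes
#'
#' The container every analysis stage operates on: a DNA sequence over
#' `{A,C,G,T,N}` with typed features holding circular coordinates.
#'
#' @param id Accession-like identifier.
#' @param sequence DNA string.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param features List of [mt_feature()] objects.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence, topology = c("circular", "linear"),
                             features = list()) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  assert_dna(sequence, paste0("genome '", id, "' sequence"))
  L <- nchar(sequence)
  g <- structure(list(id = as.character(id), sequence = sequence, length = L,
                      topology = topology, features = features),
                 class = "annotated_genome")
  validate_genome(g)
  g
}

validate_genome <- function(g) {
  ids <- vapply(g$features, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate feature ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  kinds <- vapply(g$features, `[[`, "", "kind")
  for (f in g$features) {
    if (f$interval$genome_length != g$length)
      stop("feature '", f$id, "' interval is on a ", f$interval$genome_length,
           " bp circle but genome is ", g$length, " bp", call. = FALSE)
  }
  # exon/intron must reference an existing gene
  gene_ids <- ids[kinds %in% c("gene", "tRNA", "rRNA")]
  for (f in g$features) {
    if (f$kind %in% c("exon", "intron")) {
      p <- f$attributes$parent
      if (is.null(p) || !p %in% gene_ids)
        stop(f$kind, " '", f$id, "' references missing parent gene '",
             p %||% "<none>", "'", call. = FALSE)
    }
  }
  check_gene_tiling(g, ids, kinds)
  invisible(g)
}

# introns of a gene disjoint from its exons; exons+introns tile the gene
check_gene_tiling <- function(g, ids, kinds) {
  parent_of <- vapply(g$features, function(f) f$attributes$parent %||% NA_character_, "")
  for (gi in which(kinds == "gene")) {
    gene <- g$features[[gi]]
    kid_idx <- which(!is.na(parent_of) & parent_of == gene$id &
                       kinds %in% c("exon", "intron"))
    if (length(kid_idx) == 0L) next
    L <- g$length
    gspan <- interval_span(gene$interval)
    offs <- lapply(g$features[kid_idx], function(f) {
      o <- (f$interval$start - gene$interval$start) %% L
      c(o, o + interval_span(f$interval))
    })
    m <- do.call(rbind, offs)
    m <- m[order(m[, 1L]), , drop = FALSE]
    if (any(m[, 2L] > gspan))
      stop("children of gene '", gene$id, "' extend past the gene interval", call. = FALSE)
    if (m[1L, 1L] != 0L || m[nrow(m), 2L] != gspan ||
        (nrow(m) > 1L && any(m[-1L, 1L] != m[-nrow(m), 2L])))
      stop("exons and introns of gene '", gene$id,
           "' do not tile the gene interval disjointly", call. = FALSE)
  }
  invisible(NULL)
}

#' Extract a subsequence from a circular genome
#'
#' Returns the bases covered by `interval`, concatenating the suffix and
#' prefix of the sequence when the interval wraps the origin.
#'
#' @param genome An [annotated_genome()].
#' @param interval A [circ_interval()] on the same circle.
#' @param strand `"+"` for the forward strand, `"-"` for the reverse
#'   complement.
#' @return DNA string of length `interval_span(interval)`.
#' @export
subsequence <- function(genome, interval, strand = "+") {
  if (interval$genome_length != genome$length)
    stop("interval genome_length does not match the genome", call. = FALSE)
  segs <- interval_segments(interval)
  out <- paste(substring(genome$sequence, segs[, 1L], segs[, 2L]), collapse = "")
  if (strand == "-") out <- dna_revcomp(out)
  out
}

#' Rotate the origin of a circular genome
#'
#' Moves the coordinate origin to `shift` (0-based); all feature intervals
#' are remapped.  Useful for origin-invariance checks and internal
#' linearisation.
#'
#' @param genome An [annotated_genome()].
#' @param shift New origin, 0-based position on the current coordinates.
#' @return An [annotated_genome()] whose sequence is a rotation of the input.
#' @export
rotate_genome <- function(genome, shift) {
  if (genome$topology != "circular") stop("can only rotate circular genomes")
  L <- genome$length
  shift <- as.integer(shift %% L)
  s <- genome$sequence
  seq2 <- if (shift == 0L) s else
    paste0(substring(s, shift + 1L, L), substring(s, 1L, shift))
  feats <- lapply(genome$features, function(f) {
    f$interval <- interval_from_span((f$interval$start - shift) %% L,
                                     interval_span(f$interval), L)
    f
  })
  annotated_genome(genome$id, seq2, "circular", feats)
}

#' Tabular view of genome features
#'
#' @param genome An [annotated_genome()].
#' @return A data.frame with one row per feature (0-based half-open
#'   coordinates).
#' @export
features_table <- function(genome) {
  if (length(genome$features) == 0L) {
    return(data.frame(id = character(0), kind = character(0),
                      gene_name = character(0), start = integer(0),
                      end = integer(0), span = integer(0), strand = character(0),
                      parent = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    id = vapply(genome$features, `[[`, "", "id"),
    kind = vapply(genome$features, `[[`, "", "kind"),
    gene_name = vapply(genome$features, `[[`, "", "gene_name"),
    start = vapply(genome$features, function(f) f$interval$start, 0L),
    end = vapply(genome$features, function(f) f$interval$end, 0L),
    span = vapply(genome$features, function(f) interval_span(f$interval), 0L),
    strand = vapply(genome$features, `[[`, "", "strand"),
    parent = vapply(genome$features, function(f) f$attributes$parent %||% NA_character_, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome '%s': %s, %d bp, %d features>\n",
              x$id, x$topology, x$length, length(x$features)))
  invisible(x)
}
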