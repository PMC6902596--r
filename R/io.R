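# Readers/writers.  Internal coordinates are 0-based half-open circular;
# GFF3 and GenBank stay 1-based inclusive on disk.  Origin-spanning
# features are serialized as a two-segment join (GenBank) or as two GFF3
# rows sharing one ID, and read back into a single wrapping interval.

KIND_TO_GFF <- c(gene = "gene", exon = "exon", intron = "intron",
                 tRNA = "tRNA", rRNA = "rRNA", ORF = "ORF",
                 "repeat" = "repeat_region", SSR = "microsatellite")
GFF_TO_KIND <- stats::setNames(names(KIND_TO_GFF), KIND_TO_GFF)

#' Read an annotated genome
#'
#' Reads a FASTA sequence plus GFF3 feature file, or a GenBank flat file.
#' All features are normalised to 0-based half-open circular intervals;
#' GFF3 1-based inclusive coordinates are converted, and a GenBank
#' `join()` across the origin becomes a single wrapping interval.
#'
#' @param path FASTA file (for `format = "fasta+gff3"`) or GenBank flat
#'   file (for `format = "genbank"`).
#' @param format `"fasta+gff3"` or `"genbank"`.
#' @param gff GFF3 file path (required for `"fasta+gff3"`).
#' @param topology Genome topology, `"circular"` by default.
#' @return An [annotated_genome()].
#' @export
read_genome <- function(path, format = c("fasta+gff3", "genbank"), gff = NULL,
                        topology = "circular") {
  format <- match.arg(format)
  if (format == "genbank") return(read_genbank(path))
  if (is.null(gff)) stop("format 'fasta+gff3' requires a gff file", call. = FALSE)
  fa <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("FASTA parse error in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(fa) == 0L) stop("no sequence records in '", path, "'", call. = FALSE)
  if (length(fa) > 1L) warning("multiple FASTA records; using the first")
  id <- sub("\\s.*$", "", names(fa)[1L])
  seq <- toupper(as.character(fa[[1L]]))
  feats <- read_gff3_features(gff, nchar(seq))
  annotated_genome(id, seq, topology, feats)
}

read_gff3_features <- function(gff, L) {
  l1 <- readLines(gff, n = 1L)
  if (length(l1) == 0L) return(list())
  if (!grepl("^##gff-version\\s+3", l1))
    stop("'", gff, "' lacks the ##gff-version 3 pragma", call. = FALSE)
  gr <- tryCatch(rtracklayer::import(gff, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in '", gff, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(gr) == 0L) return(list())
  df <- data.frame(
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    stringsAsFactors = FALSE)
  df$ID <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else NA_character_
  df$Name <- if ("Name" %in% names(S4Vectors::mcols(gr))) as.character(gr$Name) else NA_character_
  df$Parent <- if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1L]] else NA_character_, "")
  } else NA_character_
  if (any(df$start < 1L | df$end > L))
    stop("GFF3 feature outside [1, ", L, "]: record ",
         which(df$start < 1L | df$end > L)[1L], call. = FALSE)
  known <- df$type %in% names(GFF_TO_KIND)
  if (any(!known)) {
    warning("skipping ", sum(!known), " GFF3 record(s) of unhandled type: ",
            paste(unique(df$type[!known]), collapse = ", "))
    df <- df[known, , drop = FALSE]
  }
  if (nrow(df) == 0L) return(list())
  df$ID[is.na(df$ID)] <- paste0("feat", seq_len(sum(is.na(df$ID))))
  feats <- list()
  for (fid in unique(df$ID)) {
    rows <- df[df$ID == fid, , drop = FALSE]
    if (nrow(rows) == 1L) {
      iv <- circ_interval(rows$start - 1L, rows$end, L)
    } else if (nrow(rows) == 2L) {
      head_i <- which(rows$end == L); tail_i <- which(rows$start == 1L)
      if (length(head_i) != 1L || length(tail_i) != 1L || head_i == tail_i)
        stop("feature '", fid, "': multi-segment record is not an origin join",
             call. = FALSE)
      iv <- circ_interval(rows$start[head_i] - 1L, rows$end[tail_i], L)
      rows <- rows[head_i, , drop = FALSE]
    } else {
      stop("feature '", fid, "': more than two segments", call. = FALSE)
    }
    attrs <- list()
    if (!is.na(rows$Parent[1L])) attrs$parent <- rows$Parent[1L]
    feats[[length(feats) + 1L]] <- mt_feature(
      id = fid, kind = GFF_TO_KIND[[rows$type[1L]]], interval = iv,
      strand = if (rows$strand[1L] %in% c("+", "-")) rows$strand[1L] else "+",
      gene_name = if (is.na(rows$Name[1L])) "" else rows$Name[1L],
      attributes = attrs)
  }
  feats
}

#' Write an annotated genome as FASTA + GFF3
#'
#' Origin-spanning features are written as two GFF3 rows sharing one ID.
#' Writers are bit-stable: identical inputs give identical files.
#'
#' @param genome An [annotated_genome()].
#' @param fasta,gff Output paths.
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta, gff) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, fasta, width = 70L)
  L <- genome$length
  starts <- integer(0); ends <- integer(0); ids <- character(0)
  types <- character(0); strands <- character(0); nms <- character(0)
  parents <- character(0)
  for (f in genome$features) {
    segs <- interval_segments(f$interval)
    for (i in seq_len(nrow(segs))) {
      starts <- c(starts, segs[i, 1L]); ends <- c(ends, segs[i, 2L])
      ids <- c(ids, f$id); types <- c(types, KIND_TO_GFF[[f$kind]])
      strands <- c(strands, f$strand)
      nms <- c(nms, if (nzchar(f$gene_name)) f$gene_name else NA_character_)
      parents <- c(parents, f$attributes$parent %||% NA_character_)
    }
  }
  if (length(starts)) {
    gr <- GenomicRanges::GRanges(
      seqnames = genome$id,
      ranges = IRanges::IRanges(start = starts, end = ends),
      strand = strands)
    gr$source <- "mitorecomb"
    gr$type <- types
    gr$ID <- ids
    gr$Name <- nms
    gr$Parent <- IRanges::CharacterList(lapply(parents, function(p)
      if (is.na(p)) character(0) else p))
    GenomeInfoDb::seqlengths(gr) <- L
    GenomeInfoDb::isCircular(gr) <- genome$topology == "circular"
    rtracklayer::export(gr, gff, format = "gff3")
  } else {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", genome$id, L)), gff)
  }
  invisible(genome)
}

# ---- GenBank flat file (read-only) ------------------------------------

parse_gb_location <- function(loc, L, lineno) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    segs <- lapply(parts, function(p) as.integer(strsplit(p, "..", fixed = TRUE)[[1L]]))
    if (length(segs) == 2L && segs[[1L]][2L] == L && segs[[2L]][1L] == 1L) {
      return(list(iv = c(segs[[1L]][1L] - 1L, segs[[2L]][2L]), strand = strand))
    }
    stop("GenBank line ", lineno, ": unsupported join location '", loc, "'",
         call. = FALSE)
  }
  if (grepl("^\\d+$", loc)) {
    p <- as.integer(loc)
    return(list(iv = c(p - 1L, p), strand = strand))
  }
  se <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
  if (length(se) != 2L || anyNA(se))
    stop("GenBank line ", lineno, ": cannot parse location '", loc, "'", call. = FALSE)
  if (se[1L] < 1L || se[2L] > L)
    stop("GenBank line ", lineno, ": feature outside [1, ", L, "]", call. = FALSE)
  list(iv = c(se[1L] - 1L, se[2L]), strand = strand)
}

GB_KEY_TO_KIND <- c(gene = "gene", exon = "exon", intron = "intron",
                    tRNA = "tRNA", rRNA = "rRNA",
                    repeat_region = "repeat", microsatellite = "SSR")

read_genbank <- function(path) {
  lines <- readLines(path)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("'", path, "': no LOCUS line", call. = FALSE)
  toks <- strsplit(trimws(lines[locus_i[1L]]), "\\s+")[[1L]]
  id <- toks[2L]
  L <- as.integer(toks[3L])
  topo <- if (any(grepl("circular", toks, ignore.case = TRUE))) "circular" else "linear"
  # sequence
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0L) stop("'", path, "': no ORIGIN block", call. = FALSE)
  seq_lines <- lines[(orig_i[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(seq) != L)
    stop("'", path, "': ORIGIN has ", nchar(seq), " bases but LOCUS says ", L,
         call. = FALSE)
  # feature table
  feat_i <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_i)) {
    block <- lines[(feat_i[1L] + 1L):(orig_i[1L] - 1L)]
    # fold continuation lines (col 22+) into the entry opened at col 6
    entries <- list(); entry_lines <- integer(0)
    for (k in seq_along(block)) {
      ln <- block[k]
      if (grepl("^ {5}\\S", ln)) {
        entries[[length(entries) + 1L]] <- ln
        entry_lines <- c(entry_lines, feat_i[1L] + k)
      } else if (length(entries)) {
        entries[[length(entries)]] <- paste0(entries[[length(entries)]], "\n", ln)
      }
    }
    counter <- 0L
    for (k in seq_along(entries)) {
      e <- strsplit(entries[[k]], "\n", fixed = TRUE)[[1L]]
      head_toks <- strsplit(trimws(e[1L]), "\\s+")[[1L]]
      key <- head_toks[1L]
      if (!key %in% names(GB_KEY_TO_KIND)) next
      # location may continue over lines until the first qualifier
      qual_start <- grep("^\\s*/", e)
      loc_end <- if (length(qual_start)) qual_start[1L] - 1L else length(e)
      loc <- paste0(paste(head_toks[-1L], collapse = ""),
                    paste(trimws(e[seq_len(loc_end)][-1L]), collapse = ""))
      parsed <- parse_gb_location(loc, L, entry_lines[k])
      quals <- e[grep("^\\s*/", e)]
      getq <- function(name) {
        hit <- grep(paste0("^\\s*/", name, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub('^"|"$', "", sub(paste0("^\\s*/", name, "="), "", trimws(hit[1L])))
      }
      counter <- counter + 1L
      fid <- getq("locus_tag")
      if (is.na(fid)) fid <- paste0(key, "_", counter)
      gene <- getq("gene")
      attrs <- list()
      parent <- getq("parent")
      if (!is.na(parent)) attrs$parent <- parent
      feats[[length(feats) + 1L]] <- mt_feature(
        id = fid, kind = GB_KEY_TO_KIND[[key]],
        interval = circ_interval(parsed$iv[1L], parsed$iv[2L], L),
        strand = parsed$strand,
        gene_name = if (is.na(gene)) "" else gene,
        attributes = attrs)
    }
  }
  annotated_genome(id, seq, topo, feats)
}

# ---- FASTQ read pairs --------------------------------------------------

#' Read paired-end reads from two FASTQ files
#'
#' Mates are matched by record order; identifiers are checked to agree
#' after stripping `/1`, `/2` suffixes.
#'
#' @param fq1,fq2 FASTQ paths for mate 1 and mate 2.
#' @return A data.frame with columns `id`, `mate1`, `mate2`.
#' @export
read_fastq_pairs <- function(fq1, fq2) {
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq")
  if (length(r1) != length(r2))
    stop("mate files differ in record count (", length(r1), " vs ", length(r2), ")",
         call. = FALSE)
  strip <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  id1 <- strip(names(r1)); id2 <- strip(names(r2))
  if (!identical(id1, id2))
    stop("mate identifiers do not pair up (first mismatch: record ",
         which(id1 != id2)[1L], ")", call. = FALSE)
  data.frame(id = id1, mate1 = as.character(r1), mate2 = as.character(r2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write paired-end reads to two FASTQ files
#'
#' Qualities are written as a constant 'I' (Q40); the simulator has no
#' quality model.
#'
#' @param reads Data.frame with `id`, `mate1`, `mate2` columns.
#' @param fq1,fq2 Output FASTQ paths.
#' @return Invisibly, `reads`.
#' @export
write_fastq_pairs <- function(reads, fq1, fq2) {
  wr <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  wr(reads$mate1, paste0(reads$id, "/1"), fq1)
  wr(reads$mate2, paste0(reads$id, "/2"), fq2)
  invisible(reads)
}
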