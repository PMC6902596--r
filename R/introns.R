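# Intron presence/absence inventories under the standard mitochondrial
# intron nomenclature: host gene + "i" + insertion position in the
# spliced reference coding sequence + group tag (g1/g2), e.g. cox1i44g2.

#' Compose / parse standard intron names
#'
#' @param gene Host gene symbol.
#' @param pos Insertion position (nucleotide offset in the spliced gene).
#' @param group `"g1"`, `"g2"` or `"unknown"`.
#' @return `intron_name()`: the name string.  `parse_intron_name()`: a
#'   list with `gene`, `pos`, `group`.
#' @export
#' @examples
#' intron_name("cox1", 44, "g2")          # "cox1i44g2"
#' parse_intron_name("nad4Li100g2")$gene  # "nad4L"
intron_name <- function(gene, pos, group) {
  paste0(gene, "i", as.integer(pos), group)
}

#' @rdname intron_name
#' @param name An intron name such as `"cox1i44g2"`.
#' @export
parse_intron_name <- function(name) {
  m <- regmatches(name, regexec("^(.+?)i([0-9]+)(g[12]|unknown)$", name))[[1L]]
  if (length(m) != 4L) stop("cannot parse intron name '", name, "'", call. = FALSE)
  list(gene = m[2L], pos = as.integer(m[3L]), group = m[4L])
}

#' Load the packaged intron reference catalog
#'
#' Maps (gene, insertion position) to the canonical intron name and
#' group for the liverwort mitochondrial introns discussed in the
#' literature.
#'
#' @param path Catalog TSV (defaults to the packaged file).
#' @return Data.frame with columns `gene`, `insertion_pos`, `group`,
#'   `name`.
#' @export
load_intron_catalog <- function(path = system.file("extdata", "intron_catalog.tsv",
                                                   package = "mitorecomb")) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "insertion_pos", "group", "name") %in% names(ct)))
  ct
}

# insertion position of each intron of a genome: the cumulative spliced
# exon length upstream of the intron, within its parent gene
genome_introns <- function(genome) {
  ft <- features_table(genome)
  introns <- ft[ft$kind == "intron", , drop = FALSE]
  if (nrow(introns) == 0L) {
    return(data.frame(gene = character(0), insertion_pos = integer(0),
                      intron_id = character(0)))
  }
  L <- genome$length
  out <- list()
  for (r in seq_len(nrow(introns))) {
    parent <- introns$parent[r]
    gene_row <- ft[ft$id == parent, , drop = FALSE]
    gname <- if (nzchar(gene_row$gene_name)) gene_row$gene_name else gene_row$id
    exons <- ft[ft$kind == "exon" & !is.na(ft$parent) & ft$parent == parent, ,
                drop = FALSE]
    gstart <- gene_row$start; gstrand <- gene_row$strand
    gspan <- gene_row$span
    off <- function(s) (s - gstart) %% L
    ipos_fwd <- off(introns$start[r])
    up_exon_bp <- if (gstrand == "+") {
      sum(pmin(exons$span, pmax(0L, ipos_fwd - off(exons$start))))
    } else {
      # reverse-strand gene: spliced coordinate counts from the gene end
      iend_fwd <- ipos_fwd + introns$span[r]
      sum(pmin(exons$span, pmax(0L, (gspan - iend_fwd) -
                                  (gspan - off(exons$start) - exons$span))))
    }
    out[[length(out) + 1L]] <- data.frame(gene = gname,
                                          insertion_pos = as.integer(up_exon_bp),
                                          intron_id = introns$id[r],
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build an intron presence/absence inventory
#'
#' For a set of annotated genomes, computes per-genome presence/absence
#' over the union of observed introns, naming each intron from the
#' reference catalog keyed by (gene, insertion position).  Introns
#' absent from the catalog are named by their computed insertion
#' position with group `"unknown"` and flagged novel.
#'
#' @param genomes List of [annotated_genome()] objects (non-empty).
#' @param catalog Reference catalog (see [load_intron_catalog()]).
#' @return A data.frame of class `intron_inventory`: one row per intron
#'   (`name`, `gene`, `insertion_pos`, `group`, `novel`) plus one
#'   logical presence column per genome.  Attribute `totals` holds the
#'   per-genome intron counts.
#' @export
build_intron_inventory <- function(genomes, catalog = load_intron_catalog()) {
  if (length(genomes) == 0L) stop("no genomes supplied", call. = FALSE)
  gids <- vapply(genomes, `[[`, "", "id")
  per <- lapply(genomes, genome_introns)
  all_keys <- unique(do.call(rbind, lapply(per, function(d)
    d[, c("gene", "insertion_pos")])))
  if (is.null(all_keys) || nrow(all_keys) == 0L)
    stop("no introns found in any genome", call. = FALSE)
  all_keys <- all_keys[order(all_keys$gene, all_keys$insertion_pos), , drop = FALSE]
  hit <- match(paste(all_keys$gene, all_keys$insertion_pos),
               paste(catalog$gene, catalog$insertion_pos))
  inv <- data.frame(
    name = ifelse(is.na(hit),
                  intron_name(all_keys$gene, all_keys$insertion_pos, "unknown"),
                  catalog$name[hit]),
    gene = all_keys$gene,
    insertion_pos = all_keys$insertion_pos,
    group = ifelse(is.na(hit), "unknown", catalog$group[hit]),
    novel = is.na(hit),
    stringsAsFactors = FALSE)
  for (gi in seq_along(genomes)) {
    k <- paste(per[[gi]]$gene, per[[gi]]$insertion_pos)
    inv[[gids[gi]]] <- paste(inv$gene, inv$insertion_pos) %in% k
  }
  totals <- vapply(gids, function(g) sum(inv[[g]]), 0L)
  structure(inv, class = c("intron_inventory", "data.frame"), totals = totals)
}

#' Write an intron inventory as TSV
#'
#' One row per intron with 0/1 presence cells, plus a bottom `total` row
#' with per-genome intron counts.
#'
#' @param inventory An `intron_inventory`.
#' @param path Output path.
#' @param header Optional provenance comment lines.
#' @return Invisibly, the written data.frame.
#' @export
write_introns_tsv <- function(inventory, path, header = NULL) {
  meta <- c("name", "gene", "insertion_pos", "group", "novel")
  gcols <- setdiff(names(inventory), meta)
  df <- as.data.frame(inventory)
  for (g in gcols) df[[g]] <- as.integer(df[[g]])
  tot <- df[1L, , drop = FALSE]
  tot[, meta] <- c("total", "", NA, "", NA)
  for (g in gcols) tot[[g]] <- sum(df[[g]])
  df <- rbind(df, tot)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
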