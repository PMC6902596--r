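# Packaged machine-readable transcription of the published per-repeat
# recombination survey (26 events across 16 liverwort species).
# Percentages are stored exactly as printed; read counts are the
# authoritative raw data and the loader cross-validates the printed
# rate against the counts at the printed precision.

#' Load the packaged recombination-survey fixture
#'
#' Returns the 26 published recombination events (one per repeat with
#' read support, across 16 liverwort species) as a `recomb_events`
#' data.frame.  On load the fixture is integrity-checked (md5) and each
#' row's printed alternative-conformation percentage is recomputed from
#' the read counts; a deviation beyond the printed precision (plus a
#' 0.005 rounding allowance) is an error.  Rows whose printed master and
#' alternative percentages do not sum to 100 (one row in the published
#' table) are flagged in attribute `pct_flagged`; counts are treated as
#' authoritative.
#'
#' @param path Fixture TSV (defaults to the packaged file).
#' @param checksum Expected md5 of the fixture file, or `NULL` to skip
#'   the integrity check.
#' @return A `recomb_events` data.frame with 26 rows; `rate_pct` carries
#'   the printed alternative percentage.
#' @export
load_table2_fixture <- function(path = system.file("extdata", "table2_events.tsv",
                                                   package = "mitorecomb"),
                                checksum = table2_md5()) {
  if (!file.exists(path)) stop("fixture not found: ", path, call. = FALSE)
  if (!is.null(checksum)) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, checksum))
      stop("fixture integrity error: md5 ", got, " != expected ", checksum,
           call. = FALSE)
  }
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("species", "length_bp", "identity_pct", "direction", "copy1_pos",
            "copy2_pos", "master_count", "master_pct", "alt_count", "alt_pct",
            "gene_order_state", "genes_affected")
  if (!identical(names(df), need))
    stop("fixture has unexpected columns", call. = FALSE)
  n_dec <- function(x) {
    d <- sub("^[^.]*\\.?", "", x)
    nchar(d)
  }
  out <- data.frame(
    species = df$species,
    event_id = sprintf("t2_%02d", seq_len(nrow(df))),
    length_bp = as.integer(df$length_bp),
    identity_pct = as.numeric(df$identity_pct),
    direction = df$direction,
    copy1_pos = df$copy1_pos,
    copy2_pos = df$copy2_pos,
    master_count = as.integer(df$master_count),
    master_pct = as.numeric(df$master_pct),
    alt_count = as.integer(df$alt_count),
    alt_pct = as.numeric(df$alt_pct),
    rate_pct = as.numeric(df$alt_pct),
    gene_order_state = df$gene_order_state,
    genes_affected = ifelse(is.na(df$genes_affected), "", df$genes_affected),
    stringsAsFactors = FALSE)
  if (any(is.na(out$master_count)) || any(is.na(out$alt_count)))
    stop("fixture has non-numeric read counts", call. = FALSE)
  # printed rate must match the counts at the printed precision
  recomputed <- 100 * out$alt_count / (out$master_count + out$alt_count)
  tol <- 0.5 * 10^(-n_dec(df$alt_pct)) + 0.005
  bad <- abs(recomputed - out$alt_pct) > tol
  if (any(bad))
    stop("fixture row(s) ", paste(which(bad), collapse = ","),
         ": printed rate disagrees with read counts", call. = FALSE)
  flagged <- which(abs(out$master_pct + out$alt_pct - 100) > 0.02)
  structure(out, class = c("recomb_events", "data.frame"),
            pct_flagged = flagged)
}

table2_md5 <- function() "42f5faf3ea64c8de4d8c97ab6e444c5a"
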