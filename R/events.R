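# Recombination events (one per assayable repeat with informative read
# support) and their cohort summary statistics.

#' Assemble recombination events
#'
#' Joins repeat descriptors, read-pair support counts and structural
#' outcomes into the per-event table (species, repeat length/identity/
#' direction/positions, support counts and rate, gene-order state and
#' genes affected).  Events with no informative read pairs are dropped
#' with a message.
#'
#' @param species Species / genome identifier.
#' @param pairs A `repeat_pairs` data.frame (assayable subset).
#' @param counts_list List of `support_counts`, one per row of `pairs`.
#' @param outcomes List of `recomb_outcome` objects (from
#'   [apply_recombination()]), one per row of `pairs`, or `NULL` to leave
#'   the structural columns empty.
#' @return A data.frame of class `recomb_events`.
#' @export
recombination_events <- function(species, pairs, counts_list, outcomes = NULL) {
  L <- attr(pairs, "genome_length")
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(pairs))) {
    cnt <- counts_list[[i]]
    m <- cnt$master_pairs; a <- cnt$alternative_pairs
    if (m + a == 0L) { dropped <- dropped + 1L; next }
    pos <- function(s, e) {
      e1 <- if (e > s) e else e + L
      paste0(s + 1L, "-", e1)
    }
    out <- outcomes[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      species = species,
      event_id = pairs$id[i],
      length_bp = pairs$aligned_length[i],
      identity_pct = round(pairs$identity_pct[i], 2),
      direction = pairs$direction[i],
      copy1_pos = pos(pairs$copy1_start[i], pairs$copy1_end[i]),
      copy2_pos = pos(pairs$copy2_start[i], pairs$copy2_end[i]),
      master_count = m,
      master_pct = round(100 * m / (m + a), 2),
      alt_count = a,
      alt_pct = round(100 * a / (m + a), 2),
      rate_pct = round(100 * a / (m + a), 2),
      gene_order_state = if (is.null(out)) NA_character_ else out$gene_order_state,
      genes_affected = if (is.null(out)) "" else paste(out$genes_affected, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (dropped > 0L)
    message(dropped, " repeat(s) had no informative read pairs; dropped from events")
  df <- if (length(rows)) do.call(rbind, rows) else empty_events()
  structure(df, class = c("recomb_events", "data.frame"))
}

empty_events <- function() {
  data.frame(species = character(0), event_id = character(0),
             length_bp = integer(0), identity_pct = numeric(0),
             direction = character(0), copy1_pos = character(0),
             copy2_pos = character(0), master_count = integer(0),
             master_pct = numeric(0), alt_count = integer(0),
             alt_pct = numeric(0), rate_pct = numeric(0),
             gene_order_state = character(0), genes_affected = character(0),
             stringsAsFactors = FALSE)
}

#' Summarise a cohort of recombination events
#'
#' Computes the cohort statistics reported for repeat-mediated
#' recombination surveys: rate median/min/max, mean repeat length,
#' number and fraction of repeats over 100 bp, the median rate of small
#' (<100 bp) repeats, and 2x2 contingency tables of repeat direction
#' against gene-order change and against gene involvement.
#'
#' @param events A `recomb_events` data.frame (>= 1 row).
#' @return A list of class `recomb_summary`.
#' @export
summarize_events <- function(events) {
  if (nrow(events) == 0L) stop("no events to summarise", call. = FALSE)
  rates <- events$rate_pct
  small <- events$length_bp < 100
  affected <- nzchar(events$genes_affected) & !is.na(events$genes_affected)
  has_state <- !is.na(events$gene_order_state)
  dir_f <- factor(events$direction, levels = c("direct", "inverted"))
  ct_order <- table(direction = dir_f[has_state],
                    order_changed = factor(events$gene_order_state[has_state] == "changed",
                                           levels = c(FALSE, TRUE),
                                           labels = c("unchanged", "changed")))
  ct_genes <- table(direction = dir_f,
                    genes_affected = factor(affected, levels = c(FALSE, TRUE),
                                            labels = c("none", "affected")))
  structure(list(
    n_events = nrow(events),
    n_species = length(unique(events$species)),
    rate_median_pct = stats::median(rates),
    rate_min_pct = min(rates),
    rate_max_pct = max(rates),
    mean_repeat_length = mean(events$length_bp),
    n_repeats_gt100 = sum(events$length_bp > 100),
    pct_repeats_gt100 = 100 * mean(events$length_bp > 100),
    n_small_repeats = sum(small),
    small_repeat_rate_median_pct = if (any(small)) stats::median(rates[small]) else NA_real_,
    n_gene_order_changed = sum(events$gene_order_state == "changed", na.rm = TRUE),
    contingency_direction_by_order_change = ct_order,
    contingency_direction_by_genes_affected = ct_genes
  ), class = "recomb_summary")
}

#' @export
print.recomb_summary <- function(x, ...) {
  cat(sprintf("Recombination summary: %d events, %d species\n", x$n_events, x$n_species))
  cat(sprintf("  rates: median %.2f%%, range %.2f-%.2f%%\n",
              x$rate_median_pct, x$rate_min_pct, x$rate_max_pct))
  cat(sprintf("  repeats: mean %.0f bp, %d (%.0f%%) > 100 bp; small-repeat median rate %.2f%%\n",
              x$mean_repeat_length, x$n_repeats_gt100, x$pct_repeats_gt100,
              x$small_repeat_rate_median_pct))
  cat(sprintf("  gene order changed after %d events\n", x$n_gene_order_changed))
  cat("  direction x order change:\n")
  print(x$contingency_direction_by_order_change)
  cat("  direction x genes affected:\n")
  print(x$contingency_direction_by_genes_affected)
  invisible(x)
}

#' Write events as TSV
#'
#' @param events A `recomb_events` data.frame.
#' @param path Output path.
#' @param header Optional provenance comment lines (written with a
#'   leading `#`).
#' @return Invisibly, `events`.
#' @export
write_events_tsv <- function(events, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(events, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(events)
}
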