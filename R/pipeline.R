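# One-call orchestration of the full analysis: repeat discovery,
# recombination assay, structural outcomes, composition and intron
# profiling, with provenance-stamped TSV/JSON outputs.

#' Pipeline configuration
#'
#' Collects input paths (or a simulation config), stage parameters and
#' the output directory.  All parameters are validated before any stage
#' runs; the effective config is echoed to `provenance.json` in the
#' output directory.
#'
#' @param genome_fasta,genome_gff Input genome (FASTA + GFF3); ignored
#'   when `sim_config` is given.
#' @param reads_1,reads_2 Paired FASTQ files; ignored when `sim_config`
#'   is given.
#' @param sim_config Optional [simulation_config()]: simulate the genome
#'   and reads instead of reading files.
#' @param min_len,max_len Assayable repeat length bounds (bp).
#' @param min_identity Repeat detection identity threshold (percent).
#' @param flank Reference-panel flank (bp).
#' @param read_min_identity Read classification identity threshold.
#' @param min_flank_cov Required flank coverage of a read-pair footprint.
#' @param max_insert Maximum implied insert (bp).
#' @param orf_min_codons,ssr_min_counts Spacer profiling thresholds.
#' @param out_dir Output directory.
#' @param seed Seed recorded in provenance (simulation uses the seed in
#'   `sim_config`).
#' @param cache Reuse existing outputs when the effective config hash
#'   matches (default TRUE).
#' @param verbose Emit progress messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta = NULL, genome_gff = NULL,
                            reads_1 = NULL, reads_2 = NULL, sim_config = NULL,
                            min_len = 50, max_len = 250, min_identity = 85,
                            flank = 200, read_min_identity = 98,
                            min_flank_cov = 50, max_insert = 1000,
                            orf_min_codons = 100,
                            ssr_min_counts = c(10, 6, 5, 5, 5, 5),
                            out_dir = "mitorecomb_out", seed = 1L,
                            cache = TRUE, verbose = TRUE) {
  if (is.null(sim_config)) {
    if (is.null(genome_fasta) || is.null(genome_gff))
      stop("either sim_config or genome_fasta+genome_gff must be given", call. = FALSE)
    for (p in c(genome_fasta, genome_gff, reads_1, reads_2)) {
      if (!is.null(p) && !file.exists(p)) stop("input not found: ", p, call. = FALSE)
    }
  } else {
    stopifnot(inherits(sim_config, "simulation_config"))
  }
  stopifnot(min_len >= 1, max_len >= min_len, flank >= 1,
            min_identity > 0, min_identity <= 100,
            read_min_identity > 0, read_min_identity <= 100,
            min_flank_cov >= 1, max_insert >= 1)
  structure(list(genome_fasta = genome_fasta, genome_gff = genome_gff,
                 reads_1 = reads_1, reads_2 = reads_2, sim_config = sim_config,
                 min_len = min_len, max_len = max_len, min_identity = min_identity,
                 flank = flank, read_min_identity = read_min_identity,
                 min_flank_cov = min_flank_cov, max_insert = max_insert,
                 orf_min_codons = orf_min_codons, ssr_min_counts = ssr_min_counts,
                 out_dir = out_dir, seed = as.integer(seed), cache = cache,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: (simulate or load) genome and reads;
#' find and select assayable repeat pairs; per repeat, build the
#' reference panel, classify read pairs and estimate the recombination
#' rate; predict structural outcomes; profile composition and introns.
#' Outputs `events.tsv`, `summary.json`, `composition.tsv`,
#' `introns.tsv`, `distances.tsv` (master vs recombinant-product gene
#' orders) and `provenance.json` under `config$out_dir`.  With
#' `cache = TRUE` a rerun with an identical config reuses the existing
#' outputs (they are byte-identical either way, since every stage is
#' deterministic given the config).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `events`, `summary`, `composition`,
#'   `inventory`, `distances` and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config)[setdiff(names(config), c("out_dir", "cache",
                                                               "verbose"))])
  prov_path <- file.path(config$out_dir, "provenance.json")
  paths <- file.path(config$out_dir,
                     c("events.tsv", "summary.json", "composition.tsv",
                       "introns.tsv", "distances.tsv"))
  names(paths) <- c("events", "summary", "composition", "introns", "distances")
  if (isTRUE(config$cache) && file.exists(prov_path)) {
    old <- tryCatch(jsonlite::read_json(prov_path), error = function(e) NULL)
    if (!is.null(old) && identical(old$config_hash, unname(hash)) &&
        all(file.exists(paths))) {
      msg("config unchanged; reusing cached outputs in ", config$out_dir,
          verbose = config$verbose)
      return(invisible(list(paths = paths, cached = TRUE)))
    }
  }
  header <- sprintf("mitorecomb %s; config_hash=%s; seed=%d",
                    as.character(utils::packageVersion("mitorecomb")),
                    hash, config$seed)

  if (!is.null(config$sim_config)) {
    msg("simulating genome and reads", verbose = config$verbose)
    gen <- generate_genome(config$sim_config)
    genome <- gen$genome
    sim <- simulate_read_pairs(genome, gen$truth, config$sim_config)
    reads <- sim$reads
  } else {
    msg("loading genome and reads", verbose = config$verbose)
    genome <- read_genome(config$genome_fasta, "fasta+gff3", gff = config$genome_gff)
    reads <- if (!is.null(config$reads_1))
      read_fastq_pairs(config$reads_1, config$reads_2) else NULL
  }

  msg("finding repeat pairs", verbose = config$verbose)
  pairs <- find_repeat_pairs(genome, min_len = config$min_len,
                             min_identity = config$min_identity)
  assayable <- select_assayable_repeats(pairs, min_len = config$min_len,
                                        max_len = config$max_len)
  msg(nrow(pairs), " repeat pair(s), ", nrow(assayable), " assayable",
      verbose = config$verbose)

  counts_list <- list(); outcomes <- list()
  for (i in seq_len(nrow(assayable))) {
    panel <- build_reference_panel(genome, assayable, i, flank = config$flank)
    counts_list[[i]] <- if (is.null(reads)) {
      structure(list(pair_id = assayable$id[i], master_pairs = 0L,
                     alternative_pairs = 0L, ambiguous_pairs = 0L,
                     unmatched_pairs = 0L, skipped_singletons = 0L,
                     per_member = integer(0)), class = "support_counts")
    } else {
      classify_read_pairs(panel, reads, min_identity = config$read_min_identity,
                          min_flank_cov = config$min_flank_cov,
                          max_insert = config$max_insert)
    }
    outcomes[[i]] <- suppressWarnings(apply_recombination(genome, assayable, i))
  }
  events <- recombination_events(genome$id, assayable, counts_list, outcomes)
  write_events_tsv(events, paths["events"], header = header)

  summary <- if (nrow(events) > 0L) summarize_events(events) else
    list(n_events = 0L, n_species = 0L)
  jsonlite::write_json(summary_to_json(summary), paths["summary"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  msg("profiling composition", verbose = config$verbose)
  prof <- profile_spacers(genome, repeats = pairs,
                          orf_min_codons = config$orf_min_codons,
                          ssr_min_counts = config$ssr_min_counts)
  write_composition_tsv(list(prof), paths["composition"], header = header)

  inventory <- tryCatch(build_intron_inventory(list(genome)),
                        error = function(e) NULL)
  if (!is.null(inventory)) write_introns_tsv(inventory, paths["introns"],
                                             header = header)
  else writeLines(paste0("# ", header), paths["introns"])

  orders <- c(list(extract_gene_order(genome)),
              unlist(lapply(outcomes, `[[`, "products"), recursive = FALSE))
  dm <- distance_matrix(orders, metric = "breakpoint")
  utils::write.table(dm, paths["distances"], sep = "\t", quote = FALSE,
                     col.names = NA)

  jsonlite::write_json(list(tool = "mitorecomb",
                            version = as.character(utils::packageVersion("mitorecomb")),
                            config_hash = unname(hash), seed = config$seed),
                       prov_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(events = events, summary = summary, composition = prof,
                 inventory = inventory, distances = dm, paths = paths,
                 cached = FALSE))
}

summary_to_json <- function(s) {
  out <- unclass(s)
  for (nm in names(out)) {
    if (is.table(out[[nm]])) out[[nm]] <- as.data.frame(out[[nm]])
  }
  out
}
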