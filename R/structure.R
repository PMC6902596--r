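# Gene-order consequences of recombination and pairwise rearrangement
# distances on signed circular gene orders.

#' Signed circular gene orders
#'
#' @param genome_id Identifier.
#' @param labels Character vector of gene labels in circular order.
#' @param signs Integer vector of +1/-1 (strand).
#' @return An object of class `gene_order`.
#' @export
gene_order <- function(genome_id, labels, signs) {
  if (length(labels) == 0L) stop("gene order must be non-empty", call. = FALSE)
  if (length(labels) != length(signs)) stop("labels/signs length mismatch", call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicate gene labels", call. = FALSE)
  structure(list(genome_id = genome_id, labels = as.character(labels),
                 signs = as.integer(signs)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order '%s' (%d genes): %s>\n", x$genome_id, length(x$labels),
              paste0(ifelse(x$signs > 0, "+", "-"), x$labels, collapse = " ")))
  invisible(x)
}

#' Extract the signed circular gene order from an annotation
#'
#' Features of the requested kinds are sorted by start position on the
#' circle; the sign is the strand.  Duplicate labels are suffixed
#' deterministically (`_1`, `_2`, ...).
#'
#' @param genome An [annotated_genome()].
#' @param include_kinds Feature kinds to include (default gene/tRNA/rRNA).
#' @return A [gene_order()].
#' @export
extract_gene_order <- function(genome, include_kinds = c("gene", "tRNA", "rRNA")) {
  ft <- features_table(genome)
  ft <- ft[ft$kind %in% include_kinds, , drop = FALSE]
  if (nrow(ft) == 0L)
    stop("annotation has no features of kind ", paste(include_kinds, collapse = "/"),
         call. = FALSE)
  ft <- ft[order(ft$start, ft$end), , drop = FALSE]
  labels <- ifelse(nzchar(ft$gene_name), ft$gene_name, ft$id)
  if (anyDuplicated(labels)) {
    dup <- labels %in% labels[duplicated(labels)]
    for (lab in unique(labels[dup])) {
      at <- which(labels == lab)
      labels[at] <- paste0(lab, "_", seq_along(at))
    }
    message("duplicate gene labels suffixed deterministically")
  }
  gene_order(genome$id, labels, ifelse(ft$strand == "+", 1L, -1L))
}

# --- canonical forms and adjacencies -----------------------------------

flip_elem <- function(lab, sgn) list(lab = lab, sgn = -sgn)

# canonical key of one signed adjacency (a -> b), identified with its
# reflection (-b -> -a)
adjacency_key <- function(la, sa, lb, sb) {
  k1 <- paste0(ifelse(sa > 0, "+", "-"), la, ">", ifelse(sb > 0, "+", "-"), lb)
  k2 <- paste0(ifelse(sb > 0, "-", "+"), lb, ">", ifelse(sa > 0, "-", "+"), la)
  if (k1 <= k2) k1 else k2
}

#' Signed circular adjacency set of a gene order
#'
#' The set of neighbouring gene pairs around the circle, canonicalised so
#' that a molecule and its reflection give the same set.  This is the
#' annotation-level criterion used to call a gene order "changed".
#'
#' @param x A [gene_order()].
#' @return Sorted character vector of adjacency keys.
#' @export
adjacency_set <- function(x) {
  n <- length(x$labels)
  if (n == 1L) return(adjacency_key(x$labels, x$signs, x$labels, x$signs))
  nxt <- c(2:n, 1L)
  sort(vapply(seq_len(n), function(i)
    adjacency_key(x$labels[i], x$signs[i], x$labels[nxt[i]], x$signs[nxt[i]]), ""))
}

# canonical string of a signed circular order, up to rotation and
# reflection (reflection = reverse order, flip signs)
canonical_order_key <- function(labels, signs) {
  n <- length(labels)
  reprs <- character(0)
  for (ref in 0:1) {
    if (ref == 1L) { labels <- rev(labels); signs <- -rev(signs) }
    for (r in seq_len(n)) {
      idx <- c(r:n, if (r > 1L) 1:(r - 1L))
      reprs <- c(reprs, paste0(ifelse(signs[idx] > 0, "+", "-"), labels[idx],
                               collapse = " "))
    }
  }
  min(reprs)
}

#' Canonical form of a gene order
#'
#' @param x A [gene_order()].
#' @return Canonical string key, identical for all rotations and for the
#'   reflected molecule.
#' @export
canonical_gene_order <- function(x) canonical_order_key(x$labels, x$signs)

# --- structural outcome of one recombination event ---------------------

#' Predict the structural outcome of recombination across a repeat pair
#'
#' Recombination between the copies of an inverted repeat inverts the
#' inter-copy segment (the arc from the end of copy 1 to the start of
#' copy 2 in ascending coordinates), giving one circular product.
#' Recombination between direct repeat copies excises the inter-copy
#' segment plus one repeat copy as a second circle, giving two products.
#' Gene order is called changed iff the canonical signed adjacency set
#' over all products differs from the master's; genes affected are those
#' whose interval overlaps either repeat copy.
#'
#' @param genome An [annotated_genome()].
#' @param pairs A `repeat_pairs` data.frame.
#' @param i Row of `pairs` to apply.
#' @return A list of class `recomb_outcome`: `event_id`,
#'   `product_genomes` (list of [annotated_genome()]), `products` (their
#'   [gene_order()]s), `gene_order_state`, `genes_affected`,
#'   `high_impact` (genes fully contained in a copy), `dropped_features`.
#' @export
apply_recombination <- function(genome, pairs, i = 1L) {
  L <- genome$length
  c1 <- pair_copy(pairs, i, "copy1")
  c2 <- pair_copy(pairs, i, "copy2")
  if (interval_overlap(c1, c2) > 0L)
    stop("pair '", pairs$id[i], "' has overlapping copies", call. = FALSE)
  inverted <- pairs$direction[i] == "inverted"

  # genes affected: overlap with either copy (on the master annotation)
  ft <- features_table(genome)
  gk <- ft$kind %in% c("gene", "tRNA", "rRNA")
  genes_affected <- character(0); high_impact <- character(0)
  for (j in which(gk)) {
    gi <- circ_interval(ft$start[j], ft$end[j], L)
    ov <- max(interval_overlap(gi, c1), interval_overlap(gi, c2))
    if (ov > 0L) {
      lab <- if (nzchar(ft$gene_name[j])) ft$gene_name[j] else ft$id[j]
      genes_affected <- c(genes_affected, lab)
      if (ov == interval_span(gi)) high_impact <- c(high_impact, lab)
    }
  }

  # linearise with copy1 at the origin; copies then sit at [0,l1) and
  # [b2s, b2e) with b2e <= L
  rot <- rotate_genome(genome, c1$start)
  l1 <- interval_span(c1)
  b2s <- (c2$start - c1$start) %% L
  b2e <- b2s + interval_span(c2)
  stopifnot(b2e <= L)
  s <- rot$sequence

  dropped <- character(0)
  take_features <- function(lo, hi, new_start, flip = FALSE, new_L) {
    # features of rot fully inside [lo, hi) remapped into a product
    out <- list()
    for (f in rot$features) {
      fs <- f$interval$start
      fe <- fs + interval_span(f$interval)      # may exceed L if wrapping
      inside <- fs >= lo && fe <= hi
      if (!inside) next
      if (flip) {
        ns <- new_start + (hi - fe)
        f$strand <- if (f$strand == "+") "-" else "+"
      } else {
        ns <- new_start + (fs - lo)
      }
      f$interval <- interval_from_span(ns, fe - fs, new_L)
      out[[length(out) + 1L]] <- f
    }
    out
  }
  feature_ids_in <- function(feats) vapply(feats, `[[`, "", "id")

  products <- list()
  if (inverted) {
    # product: [0, l1) + rc([l1, b2s)) + [b2s, L)
    seq_new <- paste0(substring(s, 1L, l1),
                      dna_revcomp(substring(s, l1 + 1L, b2s)),
                      substring(s, b2s + 1L, L))
    feats <- c(take_features(0L, l1, 0L, FALSE, L),
               take_features(l1, b2s, l1, TRUE, L),
               take_features(b2s, L, b2s, FALSE, L))
    feats <- prune_orphans(feats)
    dropped <- setdiff(feature_ids_in(rot$features), feature_ids_in(feats))
    prod <- annotated_genome(paste0(genome$id, "|", pairs$id[i], "_inv"),
                             seq_new, "circular", feats)
    # rotate back to the master coordinate frame so the repeat copies sit
    # at their original positions (recombination across an inverted pair
    # is then an involution)
    products[[1L]] <- rotate_genome(prod, (L - c1$start) %% L)
    products[[1L]]$id <- prod$id
  } else {
    # excision of [l1, b2e): subcircle carries the inter-copy segment and
    # copy 2; the deleted circle keeps copy 1
    seq_del <- paste0(substring(s, 1L, l1), substring(s, b2e + 1L, L))
    Ldel <- nchar(seq_del)
    feats_del <- c(take_features(0L, l1, 0L, FALSE, Ldel),
                   take_features(b2e, L, l1, FALSE, Ldel))
    feats_del <- prune_orphans(feats_del)
    seq_sub <- substring(s, l1 + 1L, b2e)
    Lsub <- nchar(seq_sub)
    feats_sub <- prune_orphans(take_features(l1, b2e, 0L, FALSE, Lsub))
    dropped <- setdiff(feature_ids_in(rot$features),
                       c(feature_ids_in(feats_del), feature_ids_in(feats_sub)))
    products[[1L]] <- annotated_genome(paste0(genome$id, "|", pairs$id[i], "_del"),
                                       seq_del, "circular", feats_del)
    products[[2L]] <- annotated_genome(paste0(genome$id, "|", pairs$id[i], "_sub"),
                                       seq_sub, "circular", feats_sub)
  }
  if (length(dropped))
    warning("features broken at recombination junctions were dropped: ",
            paste(dropped, collapse = ", "))

  master_order <- extract_gene_order(genome)
  orders <- list(); adj <- character(0)
  for (p in products) {
    o <- tryCatch(extract_gene_order(p), error = function(e) NULL)
    if (!is.null(o)) {
      orders[[length(orders) + 1L]] <- o
      adj <- c(adj, adjacency_set(o))
    }
  }
  state <- if (setequal(adjacency_set(master_order), adj)) "unchanged" else "changed"
  structure(list(event_id = pairs$id[i], product_genomes = products,
                 products = orders, gene_order_state = state,
                 genes_affected = sort(unique(genes_affected)),
                 high_impact = sort(unique(high_impact)),
                 dropped_features = dropped),
            class = "recomb_outcome")
}

# drop exon/intron features whose parent gene is absent
prune_orphans <- function(feats) {
  ids <- vapply(feats, `[[`, "", "id")
  keep <- vapply(feats, function(f) {
    p <- f$attributes$parent
    is.null(p) || p %in% ids
  }, TRUE)
  feats[keep]
}

#' @export
print.recomb_outcome <- function(x, ...) {
  cat(sprintf("<recomb_outcome '%s': %d product(s), gene order %s; genes affected: %s>\n",
              x$event_id, length(x$product_genomes), x$gene_order_state,
              if (length(x$genes_affected)) paste(x$genes_affected, collapse = ",") else "none"))
  invisible(x)
}

# --- rearrangement distances -------------------------------------------

#' Pairwise gene-order rearrangement distance
#'
#' Both metrics compare signed circular gene orders up to rotation and
#' reflection, over the intersection of their label sets (private genes
#' are dropped; the count is reported in attribute `n_dropped`).
#' `breakpoint` counts adjacencies of `order1` absent from `order2`.
#' `inversion` is the minimum number of segment inversions transforming
#' one order into the other: exact (breadth-first search over inversion
#' moves) for up to 12 shared genes; for larger instances a
#' lower/upper bound pair is returned in attributes `lower` and `upper`
#' (value = upper bound, attribute `exact = FALSE`).
#'
#' @param order1,order2 [gene_order()] objects.
#' @param metric `"breakpoint"` or `"inversion"`.
#' @param max_genes_exact Largest instance solved exactly (default 12).
#' @return Integer distance (with attributes for inexact cases).
#' @export
rearrangement_distance <- function(order1, order2,
                                   metric = c("breakpoint", "inversion"),
                                   max_genes_exact = 12L) {
  metric <- match.arg(metric)
  shared <- intersect(order1$labels, order2$labels)
  if (length(shared) == 0L) stop("gene orders share no labels", call. = FALSE)
  n_dropped <- (length(order1$labels) - length(shared)) +
    (length(order2$labels) - length(shared))
  sub <- function(o) {
    keep <- o$labels %in% shared
    gene_order(o$genome_id, o$labels[keep], o$signs[keep])
  }
  o1 <- sub(order1); o2 <- sub(order2)
  if (metric == "breakpoint") {
    d <- length(setdiff(adjacency_set(o1), adjacency_set(o2)))
    return(structure(as.integer(d), n_dropped = n_dropped))
  }
  # relabel o2 as the signed identity 1..n and express o1 in that frame
  n <- length(shared)
  pos <- match(o1$labels, o2$labels)
  perm <- pos
  sgn <- o1$signs * o2$signs[pos]
  if (canonical_perm_key(perm, sgn) == canonical_perm_key(seq_len(n), rep(1L, n)))
    return(structure(0L, n_dropped = n_dropped, exact = TRUE))
  if (n <= max_genes_exact) {
    d <- inversion_bfs(perm, sgn)
    return(structure(d, n_dropped = n_dropped, exact = TRUE))
  }
  bk <- length(setdiff(adjacency_set(o1), adjacency_set(o2)))
  lower <- as.integer(ceiling(bk / 2))
  upper <- greedy_inversion_upper(perm, sgn)
  structure(upper, n_dropped = n_dropped, exact = FALSE,
            lower = lower, upper = upper)
}

canonical_perm_key <- function(perm, sgn) {
  canonical_order_key(as.character(perm), sgn)
}

apply_reversal <- function(perm, sgn, i, j) {
  perm[i:j] <- rev(perm[i:j])
  sgn[i:j] <- -rev(sgn[i:j])
  list(perm = perm, sgn = sgn)
}

# exact minimum inversion count by breadth-first search over canonical
# signed circular permutations
inversion_bfs <- function(perm, sgn, max_depth = 10L) {
  n <- length(perm)
  target <- canonical_perm_key(seq_len(n), rep(1L, n))
  start <- canonical_perm_key(perm, sgn)
  if (start == target) return(0L)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(start, TRUE, envir = visited)
  frontier <- list(list(perm = perm, sgn = sgn))
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (st in frontier) {
      for (i in seq_len(n)) for (j in i:n) {
        nb <- apply_reversal(st$perm, st$sgn, i, j)
        key <- canonical_perm_key(nb$perm, nb$sgn)
        if (key == target) return(depth)
        if (!exists(key, envir = visited, inherits = FALSE)) {
          assign(key, TRUE, envir = visited)
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  stop("inversion distance exceeds search depth ", max_depth, call. = FALSE)
}

# greedy upper bound: repeatedly take the reversal that most reduces the
# breakpoint count against the identity
greedy_inversion_upper <- function(perm, sgn, max_steps = NULL) {
  n <- length(perm)
  if (is.null(max_steps)) max_steps <- n + 2L
  ident_adj <- adjacency_set(gene_order("id", as.character(seq_len(n)), rep(1L, n)))
  bk <- function(p, s) {
    length(setdiff(adjacency_set(gene_order("x", as.character(p), s)), ident_adj))
  }
  steps <- 0L
  repeat {
    cur <- bk(perm, sgn)
    if (cur == 0L &&
        canonical_perm_key(perm, sgn) == canonical_perm_key(seq_len(n), rep(1L, n)))
      return(steps)
    if (steps >= max_steps) return(steps + as.integer(ceiling(cur / 2)) + 1L)
    best <- NULL; best_bk <- cur
    for (i in seq_len(n)) for (j in i:n) {
      nb <- apply_reversal(perm, sgn, i, j)
      b <- bk(nb$perm, nb$sgn)
      if (b < best_bk) { best_bk <- b; best <- nb }
    }
    if (is.null(best)) {
      # plateau: take any reversal fixing a sign and continue
      i <- which(sgn < 0)[1L]
      if (is.na(i)) return(steps + 1L)
      best <- apply_reversal(perm, sgn, i, i)
    }
    perm <- best$perm; sgn <- best$sgn
    steps <- steps + 1L
  }
}

#' Pairwise distance matrix for a set of gene orders
#'
#' @param orders Named list of [gene_order()] objects.
#' @param metric Passed to [rearrangement_distance()].
#' @return Square symmetric matrix of distances.
#' @export
distance_matrix <- function(orders, metric = "breakpoint") {
  n <- length(orders)
  ids <- vapply(orders, `[[`, "", "genome_id")
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- tryCatch(as.integer(rearrangement_distance(orders[[i]], orders[[j]],
                                                    metric = metric)),
                  error = function(e) NA_integer_)
    m[i, j] <- d; m[j, i] <- d
  }
  m
}
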