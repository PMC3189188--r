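# ---- taxonomy ---------------------------------------------------------------

#' Read a taxonomy table
#'
#' TSV with columns `taxon`, `genus`, `order`, `domain` (header required).
#'
#' @param path File path.
#' @return Tibble of class `taxonomy_table`.
#' @export
read_taxonomy <- function(path) {
  tt <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_taxonomy(tt)
}

#' Coerce a data frame to a taxonomy table
#' @param x Data frame with columns taxon, genus, order, domain.
#' @return Tibble of class `taxonomy_table`.
#' @export
as_taxonomy <- function(x) {
  need <- c("taxon", "genus", "order", "domain")
  if (!all(need %in% names(x))) {
    abort(paste0("taxonomy table needs columns: ", paste(need, collapse = ", ")))
  }
  x <- as_tibble(x)[need]
  if (anyDuplicated(x$taxon)) abort("duplicate taxon in taxonomy table")
  if (any(!nzchar(x$order) | !nzchar(x$domain))) abort("empty rank labels in taxonomy table")
  class(x) <- c("taxonomy_table", class(x))
  x
}

.rank_of <- function(taxonomy, taxa_v, rank) {
  i <- match(taxa_v, taxonomy$taxon)
  if (anyNA(i)) {
    abort(paste0("taxon missing from taxonomy: ",
                 paste(taxa_v[is.na(i)], collapse = ", ")))
  }
  taxonomy[[rank]][i]
}

# ---- supported bipartitions -------------------------------------------------

#' Highly supported bipartitions of a tree
#'
#' Nontrivial bipartitions whose support is at least `s` (supports are
#' normalised to 0--1; a threshold given on 0--100 is normalised too).
#'
#' @param tree A `phylo` carrying support values as internal-node labels.
#' @param s Support threshold in `[0, 1]` (or 0--100).
#' @return Tibble as from [bipartitions()], filtered.
#' @export
supported_bipartitions <- function(tree, s) {
  if (s > 1) s <- s / 100
  if (s < 0 || s > 1) abort("support threshold must lie in [0, 1]")
  bp <- bipartitions(tree)
  if (nrow(bp) && all(is.na(bp$support))) {
    abort("tree carries no support values; bootstrap the tree first")
  }
  bp[!is.na(bp$support) & bp$support >= s, , drop = FALSE]
}

# ---- conflict detection -----------------------------------------------------

# taxa whose side-membership differs between two incompatible bipartitions,
# after restriction to the shared taxon set: the smaller reassignment set
# over the two orientations of the second bipartition (ties broken by the
# lexicographically smaller set, so the result is deterministic and
# symmetric in the two bipartitions)
.displaced_taxa <- function(b1, b2) {
  shared <- intersect(c(b1$side_a, b1$side_b), c(b2$side_a, b2$side_b))
  a1 <- intersect(b1$side_a, shared); bb1 <- intersect(b1$side_b, shared)
  a2 <- intersect(b2$side_a, shared); bb2 <- intersect(b2$side_b, shared)
  same <- sort(c(setdiff(a1, a2), setdiff(bb1, bb2)))  # aligned orientation
  flip <- sort(c(setdiff(a1, bb2), setdiff(bb1, a2)))  # flipped orientation
  if (length(flip) < length(same)) return(flip)
  if (length(same) < length(flip)) return(same)
  if (paste(flip, collapse = ",") < paste(same, collapse = ",")) flip else same
}

#' Classify a bipartition conflict by taxonomic rank
#'
#' The displaced taxa are those whose side membership differs between the two
#' (side-aligned) bipartitions after restriction to the shared taxa. Each
#' displaced taxon is compared with its conflicting-context neighbours: the
#' non-displaced taxa on its own side of each bipartition, counting a side
#' only when it is the smaller (or tied) side — the local "conflicted area"
#' of the tree rather than everything else. If any displaced taxon sits
#' beside a different domain the conflict is `"inter-domain"`; else if
#' beside a different order, `"inter-order"`; otherwise `"intra-order"`.
#' The rule is symmetric in the two bipartitions.
#'
#' @param b1,b2 Incompatible `bipartition` objects.
#' @param taxonomy A `taxonomy_table` covering all involved taxa.
#' @return One of `"intra-order"`, `"inter-order"`, `"inter-domain"`.
#' @export
classify_conflict_rank <- function(b1, b2, taxonomy) {
  moved <- .displaced_taxa(b1, b2)
  if (!length(moved)) return("intra-order")
  shared <- intersect(c(b1$side_a, b1$side_b), c(b2$side_a, b2$side_b))
  context_of <- function(tx, bp) {
    own <- if (tx %in% bp$side_a) intersect(bp$side_a, shared) else
      intersect(bp$side_b, shared)
    other_n <- length(shared) - length(own)
    if (length(own) > other_n) return(character(0))  # large side: no local context
    setdiff(own, moved)
  }
  lab <- "intra-order"
  for (tx in moved) {
    neighbours <- unique(c(context_of(tx, b1), context_of(tx, b2)))
    if (!length(neighbours)) next
    tdom <- .rank_of(taxonomy, tx, "domain")
    tord <- .rank_of(taxonomy, tx, "order")
    ndom <- .rank_of(taxonomy, neighbours, "domain")
    nord <- .rank_of(taxonomy, neighbours, "order")
    if (any(ndom != tdom)) return("inter-domain")
    if (any(nord != tord)) lab <- "inter-order"
  }
  lab
}

#' Screen gene trees for supported bipartition conflicts
#'
#' For every pair of trees, restricts each tree's highly supported
#' bipartitions to the shared taxon set and records every mutually
#' incompatible pair (conflicts must share at least 4 taxa to be evaluable).
#' Records are rank-classified against the taxonomy.
#'
#' @param gene_trees Named list of `phylo` trees with support values.
#' @param s Support threshold (0--1).
#' @param taxonomy A `taxonomy_table`.
#' @return Tibble of class `conflict_report`: tree ids, the two bipartitions
#'   (as `A,B|C,D` strings), their supports, shared-taxon count, displaced
#'   taxa, and `rank` label; attribute `threshold` records `s`. A per-pair
#'   summary is in attribute `pair_summary`.
#' @export
screen_conflicts <- function(gene_trees, s, taxonomy) {
  if (length(gene_trees) < 2L) abort("need at least 2 trees to screen")
  ids <- names(gene_trees)
  if (is.null(ids)) ids <- sprintf("tree_%03d", seq_along(gene_trees))
  bps <- lapply(gene_trees, supported_bipartitions, s = s)
  rows <- list()
  pair_rows <- list()
  for (i in seq_along(gene_trees)) {
    for (j in seq_along(gene_trees)) {
      if (j <= i) next
      shared <- intersect(gene_trees[[i]]$tip.label, gene_trees[[j]]$tip.label)
      n_conf <- 0L
      if (length(shared) >= 4L) {
        bi <- bps[[i]]; bj <- bps[[j]]
        for (a in seq_len(nrow(bi))) {
          b1 <- bipartition(bi$side_a[[a]], bi$side_b[[a]], bi$support[a])
          for (b in seq_len(nrow(bj))) {
            b2 <- bipartition(bj$side_a[[b]], bj$side_b[[b]], bj$support[b])
            comp <- are_compatible(b1, b2)
            if (!comp) {
              n_conf <- n_conf + 1L
              moved <- .displaced_taxa(b1, b2)
              rows[[length(rows) + 1L]] <- tibble(
                tree_1 = ids[i], bipartition_1 = .bipartition_key(b1),
                support_1 = b1$support,
                tree_2 = ids[j], bipartition_2 = .bipartition_key(b2),
                support_2 = b2$support,
                shared_taxa = length(shared),
                displaced = paste(moved, collapse = ","),
                rank = classify_conflict_rank(b1, b2, taxonomy)
              )
            }
          }
        }
      }
      pair_rows[[length(pair_rows) + 1L]] <- tibble(
        tree_1 = ids[i], tree_2 = ids[j],
        shared_taxa = length(shared), conflicts = n_conf
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble(
    tree_1 = character(0), bipartition_1 = character(0), support_1 = numeric(0),
    tree_2 = character(0), bipartition_2 = character(0), support_2 = numeric(0),
    shared_taxa = integer(0), displaced = character(0), rank = character(0)
  )
  out <- dplyr::arrange(out, .data$tree_1, .data$tree_2, .data$bipartition_1,
                        .data$bipartition_2)
  class(out) <- c("conflict_report", class(out))
  attr(out, "threshold") <- if (s > 1) s / 100 else s
  attr(out, "pair_summary") <- dplyr::bind_rows(pair_rows)
  out
}

# ---- partition filtering ----------------------------------------------------

.RANK_LEVELS <- c("intra-order", "inter-order", "inter-domain")

#' Gap-mask conflicted sequences before concatenation
#'
#' For every conflict at or above the exclusion rank, the displaced taxa's
#' sequences in the two involved partitions are replaced by all-gap rows
#' (column counts are retained so the supermatrix taxon set stays constant).
#' Intra-order conflicts are preserved under the default configuration.
#'
#' @param partitions Named list of character matrices (taxa x sites); names
#'   are partition/tree ids matching the report.
#' @param report A `conflict_report` from [screen_conflicts()].
#' @param exclude_rank Minimum rank to exclude (default `"inter-order"`).
#' @return List with `partitions` (masked copies) and `exclusions` (tibble
#'   partition/taxon/reason log).
#' @export
filter_partitions <- function(partitions, report,
                              exclude_rank = c("inter-order", "inter-domain",
                                               "intra-order")) {
  exclude_rank <- match.arg(exclude_rank)
  cut <- match(exclude_rank, .RANK_LEVELS)
  log_rows <- list()
  if (nrow(report)) {
    for (r in seq_len(nrow(report))) {
      if (match(report$rank[r], .RANK_LEVELS) < cut) next
      moved <- strsplit(report$displaced[r], ",", fixed = TRUE)[[1]]
      for (pid in c(report$tree_1[r], report$tree_2[r])) {
        if (!pid %in% names(partitions)) {
          abort(paste0("report names unknown partition: ", pid))
        }
        for (tx in intersect(moved, rownames(partitions[[pid]]))) {
          partitions[[pid]][tx, ] <- "-"
          log_rows[[length(log_rows) + 1L]] <- tibble(
            partition = pid, taxon = tx,
            reason = paste0(report$rank[r], " conflict with ",
                            setdiff(c(report$tree_1[r], report$tree_2[r]), pid))
          )
        }
      }
    }
  }
  exclusions <- if (length(log_rows)) dplyr::distinct(dplyr::bind_rows(log_rows))
  else tibble(partition = character(0), taxon = character(0), reason = character(0))
  list(partitions = partitions, exclusions = exclusions)
}
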