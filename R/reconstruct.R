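# ---- supermatrix ------------------------------------------------------------

#' Concatenate a genome set into a supermatrix alignment
#'
#' Joins every family's sequences in family order into one alignment per
#' taxon, and retains the partition map (family to half-open 0-based column
#' range).
#'
#' @param gs A `genome_set`.
#' @return Object of class `supermatrix`: list with `aln` (character matrix,
#'   taxa x total columns) and `partitions` (tibble family/start/end).
#' @export
concatenate_supermatrix <- function(gs) {
  stopifnot(inherits(gs, "genome_set"))
  aln <- matrix(gs$alphabet[gs$seq], nrow = nrow(gs$seq),
                dimnames = list(rownames(gs$seq), NULL))
  structure(list(aln = aln, partitions = .family_ranges(gs)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix>", nrow(x$aln), "taxa x", ncol(x$aln), "columns in",
      nrow(x$partitions), "partitions\n")
  invisible(x)
}

#' Neighbor-joining tree of a supermatrix or genome set
#'
#' Convenience wrapper: Kimura-corrected protein distances on the
#' concatenated alignment, then [neighbor_joining()].
#'
#' @param x A `genome_set` or `supermatrix`.
#' @return A `phylo` tree.
#' @export
supermatrix_tree <- function(x) {
  if (inherits(x, "genome_set")) {
    pd <- .pdist_families(x$seq, sum(x$lengths))
    d <- .square_from_pairs(kimura_correct(pd$p[, 1L]), pd$pairs, pd$taxa)
    return(neighbor_joining(d))
  }
  neighbor_joining(protein_distance_matrix(x$aln))
}

# ---- per-family gene trees --------------------------------------------------

#' Reconstruct one tree per gene family
#'
#' Distance (NJ, Kimura-corrected) or small-scale maximum-likelihood trees
#' for every family of a genome set, in family order. ML is exhaustive and
#' limited to 8 taxa.
#'
#' @param gs A `genome_set`.
#' @param method `"NJ"` or `"ML"`.
#' @param model Substitution model for ML.
#' @return Named list of `phylo` trees (names = family ids).
#' @export
gene_tree_set <- function(gs, method = c("NJ", "ML"),
                          model = substitution_model("JTT")) {
  method <- match.arg(method)
  G <- n_families(gs)
  if (method == "ML" && length(gs$taxa) > 8L) {
    abort("ML gene trees support at most 8 taxa; use method = 'NJ'")
  }
  out <- vector("list", G)
  if (method == "NJ") {
    pd <- .pdist_families(gs$seq, gs$lengths)
    for (g in seq_len(G)) {
      d <- tryCatch(
        .square_from_pairs(kimura_correct(pd$p[, g]), pd$pairs, pd$taxa),
        error = function(e) abort(sprintf("family %s: %s", gs$family_ids[g],
                                          conditionMessage(e)))
      )
      out[[g]] <- neighbor_joining(d)
    }
  } else {
    for (g in seq_len(G)) {
      out[[g]] <- tryCatch(
        exhaustive_ml_tree(family_alignment(gs, g), model),
        error = function(e) abort(sprintf("family %s: %s", gs$family_ids[g],
                                          conditionMessage(e)))
      )
    }
  }
  names(out) <- gs$family_ids
  out
}
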