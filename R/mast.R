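# induced split keys of a projected mask set on a subset mask
.induced_keys <- function(masks, submask) {
  if (!length(masks)) return(integer(0))
  x <- bitwAnd(masks, submask)
  nsub <- .popcount(submask)
  sz <- .popcount(x)
  x <- x[sz >= 2L & sz <= nsub - 2L]
  if (!length(x)) return(integer(0))
  # orient on the lowest bit of the subset
  anchor <- bitwAnd(submask, -submask)
  flip <- bitwAnd(x, anchor) != 0L
  x[flip] <- bitwAnd(submask, bitwNot(x[flip]))
  sort(unique(x))
}

.masks_agree_on <- function(m1, m2, submask) {
  identical(.induced_keys(m1, submask), .induced_keys(m2, submask))
}

#' Maximum agreement taxon subset of two trees
#'
#' A maximum-cardinality subset of the shared taxa on which the two restricted
#' trees have identical (unrooted) topologies. Exact search enumerates taxon
#' subsets and is limited to 16 shared taxa; beyond that a greedy
#' leaf-removal heuristic is used (repeatedly drop the leaf whose removal most
#' reduces the Robinson-Foulds distance). Ties are broken by the
#' lexicographically smallest sorted label list. Trees sharing fewer than 4
#' taxa return the shared set verbatim (agreement is vacuous there).
#'
#' @param t1,t2 `phylo` objects with overlapping taxon sets.
#' @param mode `"auto"` (exact up to 16 shared taxa), `"exact"`, or
#'   `"greedy"`.
#' @return Sorted character vector of taxon labels.
#' @export
maximum_agreement_subset <- function(t1, t2, mode = c("auto", "exact", "greedy")) {
  mode <- match.arg(mode)
  shared <- sort(intersect(t1$tip.label, t2$tip.label))
  if (length(shared) < 4L) return(shared)
  ns <- length(shared)
  if (mode == "exact" && ns > 16L) {
    abort("exact agreement-subset search is limited to 16 shared taxa; use mode = 'greedy'")
  }
  if (mode == "auto") mode <- if (ns <= 16L) "exact" else "greedy"

  r1 <- restrict_to_taxa(t1, shared)
  r2 <- restrict_to_taxa(t2, shared)

  if (mode == "greedy") return(.mast_greedy(r1, r2, shared))

  m1 <- .split_masks(r1, shared)
  m2 <- .split_masks(r2, shared)
  full <- sum(bitwShiftL(1L, seq_len(ns) - 1L))
  if (.masks_agree_on(m1, m2, full)) return(shared)
  for (k in (if (ns - 1L >= 4L) seq(ns - 1L, 4L, by = -1L) else integer(0))) {
    combos <- combn(ns, k)
    hits <- list()
    for (j in seq_len(ncol(combos))) {
      sm <- sum(bitwShiftL(1L, combos[, j] - 1L))
      if (.masks_agree_on(m1, m2, sm)) hits[[length(hits) + 1L]] <- shared[combos[, j]]
    }
    if (length(hits)) {
      keys <- vapply(hits, paste, character(1), collapse = "\r")
      return(hits[[order(keys)[1]]])
    }
  }
  # below 4 taxa agreement is vacuous; smallest labels win
  shared[seq_len(3L)]
}

.mast_greedy <- function(r1, r2, shared) {
  cur <- shared
  while (length(cur) >= 4L) {
    a <- restrict_to_taxa(r1, cur)
    b <- restrict_to_taxa(r2, cur)
    if (robinson_foulds(a, b) == 0L) return(cur)
    best <- NULL; best_rf <- Inf
    for (leaf in cur) {
      rest <- setdiff(cur, leaf)
      rf <- robinson_foulds(restrict_to_taxa(r1, rest), restrict_to_taxa(r2, rest))
      if (rf < best_rf) { best_rf <- rf; best <- leaf }
    }
    cur <- setdiff(cur, best)
  }
  cur
}
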