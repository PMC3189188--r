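# ---- split masks -----------------------------------------------------------
# Internal bit-mask representation of bipartitions. Taxa are indexed by their
# position in a sorted reference vector; a split is the integer whose set bits
# mark one side. Limited to 30 taxa (32-bit integers); the general code paths
# below fall back to label-set representations.

.mask_of <- function(labels, ref) {
  idx <- match(labels, ref)
  if (anyNA(idx)) abort("label not in reference taxon set")
  sum(bitwShiftL(1L, idx - 1L))
}

.popcount16 <- local({
  tab <- vapply(0:65535, function(x) sum(bitwAnd(bitwShiftR(x, 0:15), 1L)), integer(1))
  tab
})

.popcount <- function(x) {
  .popcount16[bitwAnd(x, 65535L) + 1L] + .popcount16[bitwShiftR(x, 16L) + 1L]
}

# masks of one side of every internal-edge bipartition of `tree`, indexed on
# `ref` (sorted superset of the tree's taxa); nontrivial splits only, deduped,
# canonicalised so the side not containing ref[1] is stored
.split_masks <- function(tree, ref = sort(tree$tip.label)) {
  n <- ape::Ntip(tree)
  if (length(ref) > 30L) abort("bit-mask splits support at most 30 taxa")
  if (n < 4L) return(integer(0))
  tr <- ape::reorder.phylo(tree, "postorder")
  m <- n + tr$Nnode
  below <- integer(m)
  tipmask <- vapply(tr$tip.label, .mask_of, integer(1), ref = ref)
  below[seq_len(n)] <- tipmask
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    below[p] <- bitwOr(below[p], below[ch])
  }
  full <- below[n + 1L]
  internal_children <- tr$edge[tr$edge[, 2] > n, 2]
  masks <- below[internal_children]
  sizes <- .popcount(masks)
  nt <- .popcount(full)
  masks <- masks[sizes >= 2L & sizes <= nt - 2L]
  # canonical orientation: store the side NOT containing the smallest taxon
  anchor <- bitwAnd(full, -full)
  flip <- bitwAnd(masks, anchor) != 0L
  masks[flip] <- bitwAnd(full, bitwNot(masks[flip]))
  unique(masks)
}

# split supports aligned with .split_masks order (before dedup splits are
# unique in any singly-labelled tree, so alignment by mask is safe)
.split_mask_supports <- function(tree, ref = sort(tree$tip.label)) {
  n <- ape::Ntip(tree)
  sup <- support_values(tree)
  if (is.null(sup) || n < 4L) return(setNames(numeric(0), character(0)))
  tr <- ape::reorder.phylo(tree, "postorder")
  m <- n + tr$Nnode
  below <- integer(m)
  below[seq_len(n)] <- vapply(tr$tip.label, .mask_of, integer(1), ref = ref)
  for (i in seq_len(nrow(tr$edge))) {
    below[tr$edge[i, 1]] <- bitwOr(below[tr$edge[i, 1]], below[tr$edge[i, 2]])
  }
  full <- below[n + 1L]
  nt <- .popcount(full)
  keep <- tr$edge[, 2] > n
  masks <- below[tr$edge[keep, 2]]
  s <- sup[tr$edge[keep, 2] - n]
  sizes <- .popcount(masks)
  ok <- sizes >= 2L & sizes <= nt - 2L
  masks <- masks[ok]; s <- s[ok]
  anchor <- bitwAnd(full, -full)
  flip <- bitwAnd(masks, anchor) != 0L
  masks[flip] <- bitwAnd(full, bitwNot(masks[flip]))
  setNames(s, as.character(masks))
}

.mask_to_labels <- function(mask, ref) ref[bitwAnd(mask, bitwShiftL(1L, seq_along(ref) - 1L)) != 0L]

# ---- bipartitions -----------------------------------------------------------

#' Construct a bipartition
#'
#' A bipartition (split) is the unordered pair of disjoint taxon sets obtained
#' by cutting one internal edge of an unrooted tree. `side_a` is normalised to
#' the side containing the lexicographically smallest taxon.
#'
#' @param side_a,side_b Character vectors of taxon labels (disjoint).
#' @param support Optional support value (0--1 or 0--100; normalised to 0--1).
#' @return An object of class `bipartition`.
#' @export
bipartition <- function(side_a, side_b, support = NA_real_) {
  side_a <- sort(unique(as.character(side_a)))
  side_b <- sort(unique(as.character(side_b)))
  if (length(intersect(side_a, side_b))) abort("bipartition sides must be disjoint")
  if (!length(side_a) || !length(side_b)) abort("bipartition sides must be non-empty")
  if (!is.na(support) && support > 1) support <- support / 100
  if (side_b[1] < side_a[1]) { tmp <- side_a; side_a <- side_b; side_b <- tmp }
  structure(list(side_a = side_a, side_b = side_b, support = as.numeric(support)),
            class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat(paste(x$side_a, collapse = ","), "|", paste(x$side_b, collapse = ","))
  if (!is.na(x$support)) cat("  [", x$support, "]", sep = "")
  cat("\n")
  invisible(x)
}

# orientation-free identity key
.bipartition_key <- function(b) {
  paste(paste(b$side_a, collapse = ","), paste(b$side_b, collapse = ","), sep = "|")
}

#' Nontrivial bipartitions of a tree
#'
#' One bipartition per internal edge, with the edge's support value (taken
#' from the child-side internal-node label) when present. Trees with fewer
#' than 4 taxa, or star trees, give an empty result.
#'
#' @param tree A `phylo` object.
#' @return A tibble with list-columns `side_a`, `side_b` (sorted taxon
#'   labels) and numeric `support` (0--1 scale, `NA` when absent).
#' @export
bipartitions <- function(tree) {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  empty <- tibble(side_a = list(), side_b = list(), support = numeric(0))
  if (n < 4L) return(empty)
  labs <- sort(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tr$Nnode)
  desc[seq_len(n)] <- as.list(tr$tip.label)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  sup <- support_values(tree)
  rows <- list()
  seen <- character(0)
  for (i in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[i, 2]
    if (ch <= n) next
    a <- sort(desc[[ch]])
    b <- setdiff(labs, a)
    if (length(a) < 2L || length(b) < 2L) next
    bp <- bipartition(a, b, if (is.null(sup)) NA_real_ else sup[ch - n])
    k <- .bipartition_key(bp)
    if (k %in% seen) next
    seen <- c(seen, k)
    rows[[length(rows) + 1L]] <- bp
  }
  if (!length(rows)) return(empty)
  tibble(
    side_a = lapply(rows, `[[`, "side_a"),
    side_b = lapply(rows, `[[`, "side_b"),
    support = vapply(rows, `[[`, numeric(1), "support")
  )
}

#' Bipartition compatibility
#'
#' Two bipartitions are compatible when a single tree could display both.
#' They are first restricted to the intersection of their taxon sets; the
#' standard criterion then holds: compatible iff at least one of the four
#' pairwise side intersections is empty. A bipartition rendered trivial by
#' the restriction, or a shared taxon set smaller than 4, is compatible by
#' convention (the comparison is uninformative; flagged via the
#' `"uninformative"` attribute of the result).
#'
#' @param b1,b2 `bipartition` objects (see [bipartition()]).
#' @return Logical scalar, with attribute `uninformative`.
#' @export
are_compatible <- function(b1, b2) {
  set1 <- c(b1$side_a, b1$side_b)
  set2 <- c(b2$side_a, b2$side_b)
  shared <- intersect(set1, set2)
  res <- function(val, uninf) structure(val, uninformative = uninf)
  if (length(shared) < 4L) return(res(TRUE, TRUE))
  a1 <- intersect(b1$side_a, shared); b1s <- intersect(b1$side_b, shared)
  a2 <- intersect(b2$side_a, shared); b2s <- intersect(b2$side_b, shared)
  if (min(length(a1), length(b1s)) < 2L || min(length(a2), length(b2s)) < 2L) {
    return(res(TRUE, TRUE))
  }
  ok <- !length(intersect(a1, a2)) || !length(intersect(a1, b2s)) ||
    !length(intersect(b1s, a2)) || !length(intersect(b1s, b2s))
  res(ok, FALSE)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the nontrivial bipartition sets. Zero
#' iff the trees share the same unrooted topology (for fully resolved trees).
#' The taxon sets must be identical; restrict first otherwise.
#'
#' @param t1,t2 `phylo` objects on the same taxon set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!identical(sort(t1$tip.label), sort(t2$tip.label))) {
    abort("robinson_foulds requires identical taxon sets; use restrict_to_taxa() first")
  }
  k1 <- vapply(seq_len(nrow(b1 <- bipartitions(t1))), function(i)
    .bipartition_key(list(side_a = b1$side_a[[i]], side_b = b1$side_b[[i]])), character(1))
  k2 <- vapply(seq_len(nrow(b2 <- bipartitions(t2))), function(i)
    .bipartition_key(list(side_a = b2$side_a[[i]], side_b = b2$side_b[[i]])), character(1))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# ---- quartets ---------------------------------------------------------------

# topology state codes over a sorted 4-taxon subset
.QSTATES <- c("12|34", "13|24", "14|23", "U")

#' Quartet topology induced by a tree on four taxa
#'
#' Restricts the tree to the four taxa and reports the resolved pairing, or
#' `"unresolved"` when the restriction is a star.
#'
#' @param tree A `phylo` object.
#' @param q Character vector of 4 leaf labels, all present in the tree.
#' @return A string `"X,Y|Z,W"` (each pair sorted; the pair holding the
#'   smallest taxon first) or `"unresolved"`.
#' @export
induced_quartet_topology <- function(tree, q) {
  q <- as.character(q)
  if (length(unique(q)) != 4L) abort("q must name 4 distinct taxa")
  missing <- setdiff(q, tree$tip.label)
  if (length(missing)) abort(paste0("taxa not in tree: ", paste(missing, collapse = ", ")))
  sub <- restrict_to_taxa(tree, q)
  bp <- bipartitions(sub)
  if (!nrow(bp)) return("unresolved")
  a <- bp$side_a[[1]]; b <- bp$side_b[[1]]
  paste0(paste(a, collapse = ","), "|", paste(b, collapse = ","))
}

# fast path: quartet state of one split-mask set over precomputed subset masks.
# subsets: integer matrix 4 x K of taxon indices (1-based, sorted ascending);
# returns integer state per subset: 1="12|34", 2="13|24", 3="14|23", 4=unresolved
.quartet_states <- function(masks, subsets) {
  K <- ncol(subsets)
  states <- rep.int(4L, K)
  if (!length(masks)) return(states)
  bit <- bitwShiftL(1L, subsets - 1L)
  dim(bit) <- dim(subsets)
  smask <- bit[1, ] + bit[2, ] + bit[3, ] + bit[4, ]
  for (m in masks) {
    x <- bitwAnd(m, smask)
    hit <- which(states == 4L & .popcount(x) == 2L)
    if (!length(hit)) next
    x <- x[hit]
    b1 <- bitwAnd(x, bit[1, hit]) != 0L
    b2 <- bitwAnd(x, bit[2, hit]) != 0L
    b3 <- bitwAnd(x, bit[3, hit]) != 0L
    b4 <- bitwAnd(x, bit[4, hit]) != 0L
    st <- integer(length(hit))
    st[(b1 & b2) | (b3 & b4)] <- 1L
    st[(b1 & b3) | (b2 & b4)] <- 2L
    st[(b1 & b4) | (b2 & b3)] <- 3L
    states[hit] <- st
  }
  states
}
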