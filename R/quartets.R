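# ---- embedded quartet tally -------------------------------------------------

# count matrix (K x 4: three resolved states + unresolved) over the subset
# battery, from a list of split-mask sets; taxmasks marks each tree's taxa
.tally_states <- function(mask_list, taxmasks, subsets, ref) {
  K <- ncol(subsets)
  counts <- matrix(0L, K, 4L)
  bit <- bitwShiftL(1L, subsets - 1L)
  dim(bit) <- dim(subsets)
  smask <- bit[1, ] + bit[2, ] + bit[3, ] + bit[4, ]
  for (t in seq_along(mask_list)) {
    inside <- bitwAnd(smask, taxmasks[t]) == smask
    if (!any(inside)) next
    st <- .quartet_states(mask_list[[t]], subsets[, inside, drop = FALSE])
    idx <- which(inside)
    counts[cbind(idx, st)] <- counts[cbind(idx, st)] + 1L
  }
  counts
}

#' Tally embedded quartet topologies across gene trees
#'
#' For every 4-taxon subset of the union taxon set, each gene tree containing
#' all four taxa contributes one count to the induced topology (or to the
#' unresolved column when the restriction is a star). Trees may have
#' different, overlapping taxon sets.
#'
#' @param gene_trees List of `phylo` trees (at most 30 distinct taxa in the
#'   union).
#' @return A tibble of class `quartet_tally`: columns `t1..t4` (the subset,
#'   sorted), `w12.34`, `w13.24`, `w14.23` (counts for the pairings
#'   `t1t2|t3t4`, `t1t3|t2t4`, `t1t4|t2t3`) and `unresolved`.
#' @export
embedded_quartet_tally <- function(gene_trees) {
  if (!length(gene_trees)) abort("need at least one gene tree")
  ref <- sort(unique(unlist(lapply(gene_trees, function(t) t$tip.label))))
  if (length(ref) > 30L) abort("quartet tally supports at most 30 union taxa")
  if (length(ref) < 4L) abort("need at least 4 taxa in the union")
  subsets <- combn(length(ref), 4L)
  mask_list <- lapply(gene_trees, .split_masks, ref = ref)
  taxmasks <- vapply(gene_trees, function(t) .mask_of(t$tip.label, ref), integer(1))
  counts <- .tally_states(mask_list, taxmasks, subsets, ref)
  out <- tibble(
    t1 = ref[subsets[1, ]], t2 = ref[subsets[2, ]],
    t3 = ref[subsets[3, ]], t4 = ref[subsets[4, ]],
    w12.34 = counts[, 1], w13.24 = counts[, 2], w14.23 = counts[, 3],
    unresolved = counts[, 4]
  )
  class(out) <- c("quartet_tally", class(out))
  attr(out, "taxa") <- ref
  out
}

# ---- plurality map ----------------------------------------------------------

.state_label <- function(row, state) {
  tx <- c(row$t1, row$t2, row$t3, row$t4)
  pr <- switch(state, c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  paste0(tx[pr[1]], ",", tx[pr[2]], "|", tx[pr[3]], ",", tx[pr[4]])
}

#' Plurality topology per 4-taxon subset
#'
#' Picks, per subset, the maximum-weight resolved topology and its margin
#' (top weight minus runner-up). Exact ties between the top two resolved
#' weights mark the subset undecided; undecided subsets impose no supertree
#' constraint. Unresolved observations count toward no topology.
#'
#' @param tally A `quartet_tally` (see [embedded_quartet_tally()]).
#' @return Tibble of class `plurality_map`: `t1..t4`, integer `state`
#'   (1 = `t1t2|t3t4`, 2 = `t1t3|t2t4`, 3 = `t1t4|t2t3`, `NA` if undecided),
#'   readable `topology`, `margin`, `undecided`.
#' @export
plurality_quartet_map <- function(tally) {
  if (!nrow(tally)) abort("empty quartet tally")
  w <- cbind(tally$w12.34, tally$w13.24, tally$w14.23)
  top <- apply(w, 1, max)
  state <- apply(w, 1, which.max)
  runner <- vapply(seq_len(nrow(w)), function(i) max(w[i, -state[i]]), numeric(1))
  undecided <- (top == runner) | (top == 0)
  margin <- top - runner
  topology <- rep(NA_character_, nrow(w))
  for (i in which(!undecided)) {
    topology[i] <- .state_label(tally[i, ], state[i])
  }
  out <- tibble(
    t1 = tally$t1, t2 = tally$t2, t3 = tally$t3, t4 = tally$t4,
    state = ifelse(undecided, NA_integer_, state),
    topology = topology, margin = ifelse(undecided, 0, margin),
    undecided = undecided
  )
  class(out) <- c("plurality_map", class(out))
  attr(out, "taxa") <- attr(tally, "taxa", exact = TRUE)
  out
}

# ---- supertree search -------------------------------------------------------

# battery of all resolved unrooted topologies on `taxa` with their quartet
# state matrices; cached per taxon set
.topology_battery <- function(taxa_names) {
  key <- paste(taxa_names, collapse = "\r")
  hit <- .pw_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(taxa_names)
  cands <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa_names)
  subsets <- combn(n, 4L)
  states <- matrix(0L, length(cands), ncol(subsets))
  keys <- character(length(cands))
  for (i in seq_along(cands)) {
    masks <- .split_masks(cands[[i]], taxa_names)
    states[i, ] <- .quartet_states(masks, subsets)
    keys[i] <- .topology_key(cands[[i]])
  }
  out <- list(cands = cands, subsets = subsets, states = states, keys = keys)
  .pw_cache[[key]] <- out
  out
}

# align a plurality map to the battery's subset ordering
.pmap_vectors <- function(pmap, taxa_names, subsets) {
  idx <- cbind(match(pmap$t1, taxa_names), match(pmap$t2, taxa_names),
               match(pmap$t3, taxa_names), match(pmap$t4, taxa_names))
  if (anyNA(idx)) abort("plurality map names taxa outside the search set")
  keyfun <- function(m) paste(m[, 1], m[, 2], m[, 3], m[, 4])
  pos <- match(keyfun(idx), keyfun(t(subsets)))
  target <- rep(NA_integer_, ncol(subsets))
  margin <- rep(0, ncol(subsets))
  target[pos] <- pmap$state
  margin[pos] <- pmap$margin
  margin[is.na(target)] <- 0
  list(target = target, margin = margin)
}

#' Assemble a supertree from a plurality quartet map
#'
#' Scores candidate topologies by the summed margins of the plurality
#' quartets they satisfy. `"exhaustive"` mode enumerates all resolved
#' unrooted topologies (at most 8 taxa) and is exact; ties are broken by
#' canonical newick order. `"greedy"` mode runs quartet-joining
#' agglomeration: repeatedly merge the pair of clusters with the highest
#' summed margin support for being a cherry, rescoring after each merge.
#'
#' @param pmap A `plurality_map` (see [plurality_quartet_map()]).
#' @param mode `"exhaustive"` or `"greedy"`.
#' @return A `phylo` topology (no branch lengths) with attribute `score`.
#' @export
supertree_search <- function(pmap, mode = c("exhaustive", "greedy")) {
  mode <- match.arg(mode)
  taxa_names <- attr(pmap, "taxa", exact = TRUE)
  if (is.null(taxa_names)) {
    taxa_names <- sort(unique(c(pmap$t1, pmap$t2, pmap$t3, pmap$t4)))
  }
  n <- length(taxa_names)
  if (n < 4L) abort("supertree search needs at least 4 taxa")
  if (mode == "exhaustive") {
    if (n > 8L) abort("exhaustive supertree search supports at most 8 taxa; use mode = 'greedy'")
    bat <- .topology_battery(taxa_names)
    pv <- .pmap_vectors(pmap, taxa_names, bat$subsets)
    live <- !is.na(pv$target)
    scores <- as.numeric((bat$states[, live, drop = FALSE] ==
                            matrix(pv$target[live], nrow(bat$states),
                                   sum(live), byrow = TRUE)) %*% pv$margin[live])
    best <- max(scores)
    cand_idx <- which(scores == best)
    win <- cand_idx[order(bat$keys[cand_idx])][1]
    out <- bat$cands[[win]]
    out$edge.length <- NULL
    attr(out, "score") <- best
    return(out)
  }
  .supertree_greedy(pmap, taxa_names)
}

.supertree_greedy <- function(pmap, taxa_names) {
  n <- length(taxa_names)
  live <- !pmap$undecided
  q <- cbind(match(pmap$t1, taxa_names), match(pmap$t2, taxa_names),
             match(pmap$t3, taxa_names), match(pmap$t4, taxa_names))[live, , drop = FALSE]
  state <- pmap$state[live]
  margin <- pmap$margin[live]
  # pairs grouped together by each plurality quartet
  pair1 <- matrix(0L, nrow(q), 2L); pair2 <- matrix(0L, nrow(q), 2L)
  for (i in seq_len(nrow(q))) {
    pr <- switch(state[i], c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
    pair1[i, ] <- q[i, pr[1:2]]; pair2[i, ] <- q[i, pr[3:4]]
  }
  cl <- seq_len(n)
  subtree <- taxa_names
  minlab <- taxa_names
  active <- seq_len(n)
  while (length(active) > 3L) {
    best_score <- -Inf; best_pair <- NULL
    cherry <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(q))) {
      c1 <- cl[pair1[i, 1]]; c2 <- cl[pair1[i, 2]]
      c3 <- cl[pair2[i, 1]]; c4 <- cl[pair2[i, 2]]
      if (length(unique(c(c1, c2, c3, c4))) != 4L) next
      for (pp in list(sort(c(c1, c2)), sort(c(c3, c4)))) {
        k <- paste0(pp[1], "-", pp[2])
        cherry[[k]] <- (cherry[[k]] %||% 0) + margin[i]
      }
    }
    keys <- ls(cherry)
    if (!length(keys)) {
      # no informative quartet spans 4 clusters: join the two smallest labels
      pair_labels <- t(combn(sort(minlab[active]), 2L))[1, ]
      best_pair <- c(active[match(pair_labels[1], minlab[active])],
                     active[match(pair_labels[2], minlab[active])])
    } else {
      for (k in keys) {
        sc <- cherry[[k]]
        pp <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
        lab <- sort(c(minlab[pp[1]], minlab[pp[2]]))
        better <- sc > best_score ||
          (sc == best_score && !is.null(best_pair) &&
             paste(lab, collapse = "\r") <
             paste(sort(minlab[best_pair]), collapse = "\r"))
        if (is.null(best_pair) || better) { best_score <- sc; best_pair <- pp }
      }
    }
    i <- best_pair[1]; j <- best_pair[2]
    new_id <- length(subtree) + 1L
    subtree <- c(subtree, paste0("(", subtree[i], ",", subtree[j], ")"))
    minlab <- c(minlab, min(minlab[i], minlab[j]))
    cl[cl == i | cl == j] <- new_id
    active <- c(setdiff(active, c(i, j)), new_id)
    # extend cl indexability: cluster ids are positions in subtree
  }
  a <- active[order(minlab[active])]
  nwk <- paste0("(", subtree[a[1]], ",", subtree[a[2]], ",", subtree[a[3]], ");")
  out <- parse_newick(nwk)
  attr(out, "score") <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
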