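# ---- scaffold construction --------------------------------------------------

# K2P nucleotide distance with pairwise deletion; NA where undefined
.k2p_distance <- function(aln) {
  taxa_names <- rownames(aln)
  n <- nrow(aln)
  d <- matrix(NA_real_, n, n, dimnames = list(taxa_names, taxa_names))
  diag(d) <- 0
  valid <- aln %in% c("A", "C", "G", "T", "a", "c", "g", "t")
  dim(valid) <- dim(aln)
  up <- toupper(aln); dim(up) <- dim(aln)
  purine <- up %in% c("A", "G"); dim(purine) <- dim(aln)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      nc <- sum(ok)
      if (nc == 0L) next
      diff <- up[i, ok] != up[j, ok]
      ts <- diff & (purine[i, ok] == purine[j, ok])   # transition: within purines/pyrimidines
      P <- sum(ts) / nc
      Q <- sum(diff & !ts) / nc
      w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
      if (w1 <= 0 || w2 <= 0) next
      d[i, j] <- d[j, i] <- -0.5 * log(w1 * sqrt(w2))
    }
  }
  d
}

# tolerant per-partition corrected distance; NA where a pair has no signal
.partition_distance <- function(aln, type) {
  if (type == "nucleotide") return(.k2p_distance(aln))
  taxa_names <- rownames(aln)
  n <- nrow(aln)
  d <- matrix(NA_real_, n, n, dimnames = list(taxa_names, taxa_names))
  diag(d) <- 0
  bad <- aln %in% c("-", ".", "?", "X", "x")
  dim(bad) <- dim(aln)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !bad[i, ] & !bad[j, ]
      nc <- sum(ok)
      if (nc == 0L) next
      p <- sum(aln[i, ok] != aln[j, ok]) / nc
      if (p > 0.85) next
      d[i, j] <- d[j, i] <- -log(1 - p - 0.2 * p^2)
    }
  }
  d
}

.guess_type <- function(aln) {
  r <- unique(as.vector(toupper(aln)))
  r <- setdiff(r, c("-", ".", "?", "X", "N"))
  if (length(r) && all(r %in% c("A", "C", "G", "T", "U"))) "nucleotide" else "protein"
}

#' Build a rooted scaffold tree from concatenated partitions
#'
#' Computes a corrected distance matrix per partition (Kimura protein
#' distances for protein partitions, K2P for nucleotide partitions), combines
#' them as the partition-length-weighted average over the pairs each defines,
#' reconstructs by neighbor joining and roots on the outgroup edge.
#'
#' @param partitions Named list of character matrices sharing a taxon set
#'   (gap-masked rows tolerated; see [filter_partitions()]).
#' @param root_outgroup Character vector of outgroup taxa (must be separable
#'   by one edge of the unrooted tree).
#' @param types Optional named character vector (`"protein"` /
#'   `"nucleotide"`); guessed from residues when omitted.
#' @return A rooted `phylo` scaffold.
#' @export
build_scaffold <- function(partitions, root_outgroup, types = NULL) {
  if (!length(partitions)) abort("no partitions")
  taxa_names <- rownames(partitions[[1]])
  for (p in partitions) {
    if (!identical(sort(rownames(p)), sort(taxa_names))) {
      abort("all partitions must share one taxon set (use filter_partitions first)")
    }
  }
  if (is.null(types)) types <- vapply(partitions, .guess_type, character(1))
  num <- matrix(0, length(taxa_names), length(taxa_names),
                dimnames = list(taxa_names, taxa_names))
  den <- num
  for (k in seq_along(partitions)) {
    aln <- partitions[[k]][taxa_names, , drop = FALSE]
    dk <- .partition_distance(aln, types[k])
    w <- ncol(aln)
    ok <- !is.na(dk)
    num[ok] <- num[ok] + w * dk[ok]
    den[ok] <- den[ok] + w
  }
  if (any(den == 0 & upper.tri(den))) {
    bad <- which(den == 0 & upper.tri(den), arr.ind = TRUE)[1, ]
    abort(sprintf("no partition defines a distance for pair %s / %s",
                  taxa_names[bad[1]], taxa_names[bad[2]]))
  }
  d <- num / pmax(den, 1)
  tree <- neighbor_joining(d)
  root_on_outgroup(tree, root_outgroup)
}

#' Root an unrooted tree on an outgroup edge
#' @param tree Unrooted `phylo`.
#' @param outgroup Character vector of outgroup taxa; must be one side of an
#'   edge of the tree.
#' @return Rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!length(outgroup) || !all(outgroup %in% tree$tip.label)) {
    abort("outgroup must be a non-empty subset of the tree's taxa")
  }
  if (length(outgroup) > 1L) {
    ref <- sort(tree$tip.label)
    masks <- .split_masks(tree, ref)
    og <- .mask_of(outgroup, ref)
    full <- .mask_of(ref, ref)
    anchor <- bitwAnd(full, -full)
    key <- if (bitwAnd(og, anchor) != 0L) bitwAnd(full, bitwNot(og)) else og
    sep <- length(outgroup) == 1L || length(outgroup) == length(ref) - 1L ||
      key %in% masks
    if (!sep) abort("outgroup is not separable by any edge; cannot root")
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# ---- scaffold edge table ----------------------------------------------------

#' Stable edge table of a rooted scaffold
#'
#' Edges carry stable ids (their postorder index) so reticulation
#' attachments are reproducible across runs.
#'
#' @param scaffold Rooted `phylo`.
#' @return Tibble: `edge_id`, `parent`, `child` (internal nodes named
#'   `n<id>`, tips by label), `length`, and list-column `clade` (tip labels
#'   below the edge).
#' @export
scaffold_edges <- function(scaffold) {
  tr <- ape::reorder.phylo(scaffold, "postorder")
  n <- ape::Ntip(tr)
  desc <- vector("list", n + tr$Nnode)
  desc[seq_len(n)] <- as.list(tr$tip.label)
  for (i in seq_len(nrow(tr$edge))) {
    desc[[tr$edge[i, 1]]] <- c(desc[[tr$edge[i, 1]]], desc[[tr$edge[i, 2]]])
  }
  node_name <- function(v) if (v <= n) tr$tip.label[v] else paste0("n", v)
  tibble(
    edge_id = seq_len(nrow(tr$edge)),
    parent = vapply(tr$edge[, 1], node_name, character(1)),
    child = vapply(tr$edge[, 2], node_name, character(1)),
    length = if (is.null(tr$edge.length)) NA_real_ else tr$edge.length,
    clade = lapply(tr$edge[, 2], function(v) sort(desc[[v]]))
  )
}

# edge id whose clade is exactly `tips`, else the edge above their MRCA
.attachment_edge <- function(edges, tips) {
  tips <- sort(tips)
  hit <- which(vapply(edges$clade, identical, logical(1), y = tips))
  if (length(hit)) return(edges$edge_id[hit[1]])
  # smallest clade containing all tips
  cont <- which(vapply(edges$clade, function(cl) all(tips %in% cl), logical(1)))
  if (!length(cont)) return(NA_integer_)  # attaches at the root
  sizes <- vapply(edges$clade[cont], length, integer(1))
  edges$edge_id[cont[which.min(sizes)]]
}

# ---- reticulation detection -------------------------------------------------

#' Detect reticulation candidates for one gene tree
#'
#' Compares a gene-family tree against the rooted scaffold restricted to the
#' gene's taxa. When some highly supported gene bipartition conflicts with
#' the scaffold, the maximum agreement subset is computed; the displaced
#' taxa (its complement) are grouped into maximal gene-tree clades, and each
#' clade yields a candidate reticulation: target attachment = the clade's
#' scaffold position, source attachment = the scaffold position of its
#' nearest-neighbour (sister) clade in the gene tree. Candidates whose
#' supporting gene-tree bipartition has support below `s` are discarded
#' (absent supports count as 1).
#'
#' @param scaffold Rooted `phylo`.
#' @param gene_tree `phylo`; taxa must be a subset of the scaffold's.
#' @param s Support threshold in `[0, 1]`.
#' @param family Family id recorded as evidence.
#' @return Tibble: `family`, `moved` (list-column of taxa), `source_edge`,
#'   `target_edge`, `support`. Zero rows when the gene agrees with the
#'   scaffold; attribute `skipped` carries a reason when not evaluable.
#' @export
detect_reticulations <- function(scaffold, gene_tree, s = 0.95, family = "fam") {
  empty <- tibble(family = character(0), moved = list(),
                  source_edge = integer(0), target_edge = integer(0),
                  support = numeric(0))
  extra <- setdiff(gene_tree$tip.label, scaffold$tip.label)
  if (length(extra)) abort(paste0("gene tree taxa absent from scaffold: ",
                                  paste(extra, collapse = ", ")))
  shared <- intersect(scaffold$tip.label, gene_tree$tip.label)
  if (length(shared) < 4L) {
    attr(empty, "skipped") <- "fewer than 4 shared taxa"
    return(empty)
  }
  rs <- restrict_to_taxa(scaffold, shared)
  ref <- sort(shared)
  sm <- .split_masks(rs, ref)
  gm <- .split_masks(gene_tree, ref)
  gsup <- .split_mask_supports(gene_tree, ref)
  supp_of <- function(mask) {
    v <- gsup[as.character(mask)]
    if (length(v) == 0L || is.na(v)) 1 else unname(v)
  }
  strong <- gm[vapply(gm, function(m) supp_of(m) >= s, logical(1))]
  conflict <- any(!strong %in% sm)
  if (!conflict) return(empty)

  agree <- maximum_agreement_subset(rs, gene_tree)
  displaced <- setdiff(shared, agree)
  if (!length(displaced)) return(empty)

  # maximal gene-tree clades inside the displaced set
  sides <- list()
  full <- .mask_of(ref, ref)
  for (m in gm) {
    sides[[length(sides) + 1L]] <- .mask_to_labels(m, ref)
    sides[[length(sides) + 1L]] <- .mask_to_labels(bitwAnd(full, bitwNot(m)), ref)
  }
  sides <- c(sides, as.list(gene_tree$tip.label))
  sides <- Filter(function(sd) all(sd %in% displaced), sides)
  sides <- sides[order(-vapply(sides, length, integer(1)))]
  clades <- list()
  covered <- character(0)
  for (sd in sides) {
    if (!length(intersect(sd, covered))) {
      clades[[length(clades) + 1L]] <- sort(sd)
      covered <- c(covered, sd)
    }
  }

  edges <- scaffold_edges(scaffold)
  og_root <- sort(agree)[1]  # deterministic rooting for sister lookup
  rg <- ape::root(gene_tree, outgroup = og_root, resolve.root = TRUE)
  rows <- list()
  for (clade in clades) {
    stem_mask <- .mask_of(clade, ref)
    anchor <- bitwAnd(full, -full)
    key <- if (bitwAnd(stem_mask, anchor) != 0L) bitwAnd(full, bitwNot(stem_mask)) else stem_mask
    sup <- if (length(clade) == 1L) {
      # pendant edge: support of the smallest surrounding split
      1
    } else supp_of(key)
    if (sup < s) next
    sister <- .sister_tips(rg, clade)
    sister_ctx <- intersect(sister, agree)
    if (!length(sister_ctx)) sister_ctx <- sister
    src <- .attachment_edge(edges, sister_ctx)
    tgt <- .attachment_edge(edges, clade)
    rows[[length(rows) + 1L]] <- tibble(
      family = family, moved = list(clade),
      source_edge = src, target_edge = tgt, support = sup
    )
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}

# tip set of the sibling subtree of the clade with tip set `tips` in a
# rooted tree (tips must form a clade)
.sister_tips <- function(rtree, tips) {
  n <- ape::Ntip(rtree)
  node <- if (length(tips) == 1L) which(rtree$tip.label == tips) else
    ape::getMRCA(rtree, tips)
  parent <- rtree$edge[rtree$edge[, 2] == node, 1]
  if (!length(parent)) return(setdiff(rtree$tip.label, tips))
  sibs <- setdiff(rtree$edge[rtree$edge[, 1] == parent, 2], node)
  out <- character(0)
  for (sb in sibs) {
    out <- c(out, if (sb <= n) rtree$tip.label[sb] else
      ape::extract.clade(rtree, sb)$tip.label)
  }
  sort(out)
}

# ---- network assembly -------------------------------------------------------

#' Assemble a reticulated network from candidate lists
#'
#' Merges candidates with identical (source, target, moved-taxa), keeps those
#' backed by at least `min_family_support` families, and attaches them as
#' directed reticulation edges on the rooted scaffold.
#'
#' @param scaffold Rooted `phylo`.
#' @param candidates Tibble of candidates (rows as produced by
#'   [detect_reticulations()], possibly across many families).
#' @param min_family_support Minimum number of supporting families.
#' @return Object of class `reticulated_network`: list with `scaffold`,
#'   `edges` (the scaffold edge table) and `reticulations` (tibble with
#'   `source_edge`, `target_edge`, `moved` list-column, `n_families`,
#'   `families` list-column, `dropped` attribute logs sub-threshold
#'   candidates).
#' @export
assemble_network <- function(scaffold, candidates, min_family_support = 5L) {
  edges <- scaffold_edges(scaffold)
  if (is.null(candidates) || !nrow(candidates)) {
    ret <- tibble(source_edge = integer(0), target_edge = integer(0),
                  moved = list(), n_families = integer(0), families = list())
  } else {
    candidates$moved_key <- vapply(candidates$moved, paste, character(1), collapse = ",")
    grp <- dplyr::group_by(candidates, .data$source_edge, .data$target_edge,
                           .data$moved_key)
    ret <- dplyr::summarise(
      grp,
      moved = list(sort(unique(unlist(.data$moved)))),
      n_families = dplyr::n_distinct(.data$family),
      families = list(sort(unique(.data$family))),
      .groups = "drop"
    )
    ret <- dplyr::select(ret, -"moved_key")
  }
  dropped <- ret[ret$n_families < min_family_support, , drop = FALSE]
  kept <- ret[ret$n_families >= min_family_support, , drop = FALSE]
  structure(
    list(scaffold = scaffold, edges = edges, reticulations = kept,
         dropped = dropped, min_family_support = min_family_support),
    class = "reticulated_network"
  )
}

#' @export
print.reticulated_network <- function(x, ...) {
  cat("<reticulated_network>", ape::Ntip(x$scaffold), "taxa,",
      nrow(x$reticulations), "reticulation(s) ( min support",
      x$min_family_support, "families )\n")
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

#' Serialise a reticulated network
#'
#' Produces two coordinated representations: an extended newick string in
#' which each reticulation appears as a `#H<k>`-labelled node (once at its
#' target clade, once as a leaf grafted into the source edge), and an
#' edge-list tibble (tree edges plus reticulation rows) from which
#' [read_network()] reconstructs an identical network.
#'
#' @param net A `reticulated_network`.
#' @param path Optional path prefix; writes `<path>.enwk` and `<path>.tsv`.
#' @return List with `newick` (string) and `edges` (tibble), invisibly when
#'   `path` is given.
#' @export
write_network <- function(net, path = NULL) {
  edges <- net$edges
  tree_rows <- dplyr::mutate(
    edges[c("edge_id", "parent", "child", "length")],
    kind = "tree", moved = "", evidence = 0L,
    edge_id = as.character(.data$edge_id)
  )
  ret <- net$reticulations
  ret_rows <- if (nrow(ret)) tibble(
    edge_id = paste0("R", seq_len(nrow(ret))),
    parent = as.character(ret$source_edge),
    child = as.character(ret$target_edge),
    length = NA_real_, kind = "reticulation",
    moved = vapply(ret$moved, paste, character(1), collapse = ","),
    evidence = as.integer(ret$n_families)
  ) else NULL
  tab <- dplyr::bind_rows(tree_rows, ret_rows)
  nwk <- .extended_newick(net)
  if (!is.null(path)) {
    writeLines(nwk, paste0(path, ".enwk"))
    readr::write_tsv(tab, paste0(path, ".tsv"), progress = FALSE)
    return(invisible(list(newick = nwk, edges = tab)))
  }
  list(newick = nwk, edges = tab)
}

.extended_newick <- function(net) {
  tr <- ape::reorder.phylo(net$scaffold, "postorder")
  n <- ape::Ntip(tr)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  lens <- setNames(tr$edge.length %||% rep(NA_real_, nrow(tr$edge)),
                   paste0(tr$edge[, 1], "-", tr$edge[, 2]))
  ret <- net$reticulations
  # per scaffold edge: #H labels anchored at target, grafted into source
  target_lab <- setNames(rep("", nrow(tr$edge)), as.character(seq_len(nrow(tr$edge))))
  source_graft <- setNames(rep("", nrow(tr$edge)), as.character(seq_len(nrow(tr$edge))))
  if (nrow(ret)) for (k in seq_len(nrow(ret))) {
    tgt <- as.character(ret$target_edge[k]); src <- as.character(ret$source_edge[k])
    target_lab[tgt] <- paste0(target_lab[tgt], "#H", k)
    source_graft[src] <- paste0(source_graft[src],
                                if (nzchar(source_graft[src])) "," else "", "#H", k)
  }
  edge_index <- setNames(seq_len(nrow(tr$edge)),
                         paste0(tr$edge[, 1], "-", tr$edge[, 2]))
  build <- function(v, parent) {
    core <- if (v <= n) tr$tip.label[v] else {
      paste0("(", paste(vapply(kids[[as.character(v)]], build, character(1),
                               parent = v), collapse = ","), ")")
    }
    if (is.na(parent)) return(core)
    eid <- as.character(edge_index[paste0(parent, "-", v)])
    lab <- target_lab[eid]
    len <- lens[paste0(parent, "-", v)]
    lenstr <- if (is.na(len)) "" else sprintf(":%.6f", len)
    node <- paste0(core, lab, lenstr)
    if (nzchar(source_graft[eid])) {
      node <- paste0("(", node, ",", source_graft[eid], ")")
    }
    node
  }
  root <- n + 1L
  paste0("(", paste(vapply(kids[[as.character(root)]], build, character(1),
                           parent = root), collapse = ","), ");")
}

#' Read a reticulated network back from its edge-list TSV
#'
#' @param path Path to the `.tsv` written by [write_network()].
#' @return A `reticulated_network`.
#' @export
read_network <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           edge_id = "c", parent = "c", child = "c",
                           length = "d", kind = "c", moved = "c", evidence = "i"))
  tre <- tab[tab$kind == "tree", , drop = FALSE]
  kids <- split(seq_len(nrow(tre)), tre$parent)
  roots <- setdiff(unique(tre$parent), tre$child)
  if (length(roots) != 1L) abort("edge table does not describe a single rooted tree")
  build <- function(node) {
    rows <- kids[[node]]
    if (is.null(rows)) return(node)
    parts <- vapply(rows, function(r) {
      sub <- build(tre$child[r])
      len <- tre$length[r]
      paste0(sub, if (is.na(len)) "" else sprintf(":%.6f", len))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  scaffold <- parse_newick(paste0(build(roots), ";"))
  retr <- tab[tab$kind == "reticulation", , drop = FALSE]
  ret <- if (nrow(retr)) tibble(
    source_edge = as.integer(retr$parent),
    target_edge = as.integer(retr$child),
    moved = lapply(strsplit(retr$moved, ",", fixed = TRUE), sort),
    n_families = retr$evidence,
    families = replicate(nrow(retr), character(0), simplify = FALSE)
  ) else tibble(source_edge = integer(0), target_edge = integer(0),
                moved = list(), n_families = integer(0), families = list())
  structure(
    list(scaffold = scaffold, edges = scaffold_edges(scaffold),
         reticulations = ret, dropped = ret[0, ], min_family_support = NA_integer_),
    class = "reticulated_network"
  )
}
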