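#' Parse a newick string into a phylogenetic tree
#'
#' Reads a newick description, with optional branch lengths and internal-node
#' support labels, into an [ape::phylo] object. Support values may be given on
#' either the 0--1 or the 0--100 scale; they are kept as node labels and
#' normalised to 0--1 by every function that consumes them. A tree whose basal
#' node is a bifurcation is treated as rooted, a basal multifurcation as
#' unrooted.
#'
#' @param text A single newick string, terminated by `;`.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1)90:0.5,C:1,D:1);")
#' ape::is.rooted(tr)
#' @seealso [write_newick()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_newick_syntax(text)
  # single-leaf degenerate tree, which the general parser cannot represent
  if (grepl("^\\s*[^(),:;]+\\s*;\\s*$", text)) {
    lab <- trimws(sub(";.*$", "", text))
    tree <- structure(
      list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = lab, Nnode = 1L),
      class = "phylo", order = "cladewise"
    )
    return(validate_tree(tree))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort("newick parse error: unreadable tree string")
  validate_tree(tree)
  tree
}

# cheap structural pre-check so malformed strings fail with a character position
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("newick parse error: unbalanced ')' at character %d", i))
      }
    }
  }
  if (depth > 0L) {
    abort(sprintf(
      "newick parse error: %d unclosed '(' at end of string (length %d)",
      depth, length(chars)
    ))
  }
  if (!grepl(";", text, fixed = TRUE)) {
    abort(sprintf(
      "newick parse error: missing ';' terminator at character %d",
      length(chars) + 1L
    ))
  }
  invisible(TRUE)
}

#' Validate the structural invariants of a tree
#'
#' Checks leaf-label uniqueness and non-negativity of branch lengths; errors
#' on violation. Used by [parse_newick()] and on entry to most operations.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("expected a 'phylo' tree object")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(tree$tip.label))) abort("empty leaf label")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    abort("negative branch length")
  }
  invisible(tree)
}

#' List the taxa (leaf labels) of a tree
#' @param tree A `phylo` object.
#' @return Character vector of leaf labels, sorted.
#' @export
taxa <- function(tree) sort(tree$tip.label)

#' Normalised support values per internal node
#'
#' Internal-node labels are read as support values; values above 1 are taken
#' to be percentages and divided by 100. Non-numeric or empty labels give
#' `NA`.
#'
#' @param tree A `phylo` object.
#' @return Numeric vector, one entry per internal node (ape node order), or
#'   `NULL` when the tree carries no node labels.
#' @export
support_values <- function(tree) {
  if (is.null(tree$node.label)) return(NULL)
  s <- suppressWarnings(as.numeric(tree$node.label))
  ifelse(!is.na(s) & s > 1, s / 100, s)
}

# adjacency view of a phylo: list of integer neighbour vectors, plus maps
# keyed "min-max" on node pairs for branch length and support
.tree_adjacency <- function(tree) {
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  adj <- vector("list", m)
  key <- function(a, b) paste0(pmin(a, b), "-", pmax(a, b))
  len <- list()
  sup <- list()
  supports <- support_values(tree)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    k <- key(a, b)
    if (!is.null(tree$edge.length)) len[[k]] <- tree$edge.length[i]
    if (!is.null(supports) && b > n) sup[[k]] <- supports[b - n]
  }
  list(n = n, adj = adj, len = len, sup = sup, key = key)
}

#' Write a tree as a canonical newick string
#'
#' Produces a deterministic newick form: at every node the children are
#' ordered by their lexicographically smallest descendant leaf label, and an
#' unrooted tree is written from the internal node adjacent to the overall
#' smallest leaf label. Two trees with the same (unrooted) topology therefore
#' yield identical topology strings, so string equality doubles as a topology
#' test. Branch lengths print with 6 decimals; supports (normalised to 0--1)
#' print as internal-node labels.
#'
#' @param tree A `phylo` object.
#' @param lengths Include branch lengths (default: yes, when present).
#' @param supports Include support labels (default: yes, when present).
#' @return A single newick string.
#' @examples
#' write_newick(parse_newick("(D,(B,A),C);"), lengths = FALSE)
#' @export
write_newick <- function(tree, lengths = TRUE, supports = TRUE) {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  if (n == 1L) return(paste0(tree$tip.label, ";"))
  at <- .tree_adjacency(tree)
  use_len <- lengths && !is.null(tree$edge.length)
  use_sup <- supports && !is.null(support_values(tree))

  fmt_len <- function(a, b) {
    if (!use_len) return("")
    l <- at$len[[at$key(a, b)]]
    if (is.null(l)) "" else sprintf(":%.6f", l)
  }
  fmt_sup <- function(a, b) {
    if (!use_sup) return("")
    s <- at$sup[[at$key(a, b)]]
    if (is.null(s) || is.na(s)) "" else format(s, digits = 6)
  }
  min_lab <- function(node, parent) {
    if (node <= n) return(tree$tip.label[node])
    kids <- setdiff(at$adj[[node]], parent)
    min(vapply(kids, min_lab, character(1), parent = node))
  }
  build <- function(node, parent) {
    if (node <= n) {
      return(paste0(tree$tip.label[node], fmt_len(parent, node)))
    }
    kids <- setdiff(at$adj[[node]], parent)
    parts <- vapply(kids, build, character(1), parent = node)
    ord <- order(vapply(kids, min_lab, character(1), parent = node))
    paste0("(", paste(parts[ord], collapse = ","), ")",
           fmt_sup(parent, node), fmt_len(parent, node))
  }

  root <- n + 1L
  rooted <- length(at$adj[[root]]) == 2L
  if (rooted) {
    start <- root
  } else {
    # virtual root: internal node adjacent to the smallest leaf label
    small_tip <- which(tree$tip.label == min(tree$tip.label))
    start <- at$adj[[small_tip]][1]
  }
  kids <- at$adj[[start]]
  kids <- kids[order(vapply(kids, min_lab, character(1), parent = start))]
  parts <- vapply(kids, build, character(1), parent = start)
  paste0("(", paste(parts, collapse = ","), ");")
}

# canonical topology-only string, the package's topology identity key
.topology_key <- function(tree) write_newick(tree, lengths = FALSE, supports = FALSE)

#' Test whether two trees share the same unrooted topology
#' @param t1,t2 `phylo` objects on the same taxon set.
#' @return Logical.
#' @export
same_topology <- function(t1, t2) {
  if (!identical(sort(t1$tip.label), sort(t2$tip.label))) return(FALSE)
  unrooted <- function(t) {
    if (ape::Ntip(t) > 2L && ape::is.rooted(t)) ape::unroot(t) else t
  }
  identical(.topology_key(unrooted(t1)), .topology_key(unrooted(t2)))
}

#' Restrict a tree to a subset of its taxa
#'
#' Prunes all leaves outside `keep` and suppresses the resulting degree-2
#' nodes, summing branch lengths across suppressed nodes (the induced
#' subtree).
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain (must be a subset of
#'   the tree's taxa).
#' @return The induced `phylo` subtree.
#' @export
restrict_to_taxa <- function(tree, keep) {
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    abort(paste0("taxa not in tree: ", paste(missing, collapse = ", ")))
  }
  if (length(keep) == ape::Ntip(tree)) return(tree)
  was_rooted <- ape::is.rooted(tree)
  out <- ape::keep.tip(tree, keep)
  # pruning an unrooted tree can leave a degree-2 basal node; suppress it so
  # the result stays unrooted
  if (!was_rooted && ape::Ntip(out) > 2L && ape::is.rooted(out)) {
    out <- ape::unroot(out)
  }
  out
}

#' Generate a random resolved tree (testing utility)
#'
#' Random unrooted resolved topology with exponential branch lengths and
#' uniform supports; used by the property-style tests.
#'
#' @param n Number of leaves.
#' @param labels Optional leaf labels (default `t1..tn`).
#' @param lengths,supports Attach random branch lengths / supports.
#' @return A `phylo` object.
#' @export
random_tree <- function(n, labels = NULL, lengths = TRUE, supports = FALSE) {
  if (is.null(labels)) labels <- sprintf("t%02d", seq_len(n))
  tree <- ape::rtree(n, rooted = FALSE, tip.label = sample(labels))
  tree$edge.length <- if (lengths) round(rexp(nrow(tree$edge), 5) + 0.01, 6) else NULL
  if (supports) {
    tree$node.label <- c("", sprintf("%.2f", runif(tree$Nnode - 1L)))
  }
  tree
}
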