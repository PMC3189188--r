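# ---- protein distances ------------------------------------------------------

#' Kimura correction for protein distances
#'
#' Maps an observed proportion of differing sites `p` to an estimated
#' distance `d = -ln(1 - p - 0.2 p^2)` (substitutions per site). Valid for
#' `p <= 0.85`; beyond that the correction saturates and an error is raised.
#'
#' @param p Numeric vector of observed difference proportions in `[0, 1]`.
#' @return Corrected distances, same shape as `p`.
#' @examples
#' kimura_correct(0.1)   # 0.1075896...
#' @export
kimura_correct <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p must lie in [0, 1]")
  if (any(p > 0.85, na.rm = TRUE)) {
    abort("saturated protein distance: observed p > 0.85 cannot be Kimura-corrected")
  }
  -log(1 - p - 0.2 * p^2)
}

#' Pairwise protein distance matrix of an alignment
#'
#' Observed difference proportions `p` with pairwise deletion of
#' gap/ambiguity sites (`-`, `.`, `?`, `X`), and Kimura-corrected distances
#' `d`. Errors when a pair has no comparable site or a saturated `p > 0.85`,
#' naming the offending pair.
#'
#' @param aln Character matrix (taxa x sites) of residues, rownames = taxa.
#' @return Object of class `protein_dist`: list with `taxa`, matrix `p`,
#'   matrix `d`.
#' @export
protein_distance_matrix <- function(aln) {
  if (is.null(rownames(aln))) abort("alignment must have taxon rownames")
  if (nrow(aln) < 2L) abort("need at least 2 sequences")
  taxa_names <- rownames(aln)
  n <- nrow(aln)
  bad <- aln %in% c("-", ".", "?", "X", "x")
  dim(bad) <- dim(aln)
  p <- matrix(0, n, n, dimnames = list(taxa_names, taxa_names))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !bad[i, ] & !bad[j, ]
      nc <- sum(ok)
      if (nc == 0L) {
        abort(sprintf("no comparable sites for pair %s / %s", taxa_names[i], taxa_names[j]))
      }
      pij <- sum(aln[i, ok] != aln[j, ok]) / nc
      if (pij > 0.85) {
        abort(sprintf("saturated distance (p = %.3f) for pair %s / %s",
                      pij, taxa_names[i], taxa_names[j]))
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  structure(list(taxa = taxa_names, p = p, d = kimura_correct(p)),
            class = "protein_dist")
}

#' @export
print.protein_dist <- function(x, ...) {
  cat("<protein_dist>", length(x$taxa), "taxa; max p =", max(x$p), "\n")
  invisible(x)
}

# fast core: per-family p-distance from an integer-coded genome set matrix.
# Returns a list: pairs (2 x P index matrix) and p (P x G matrix).
.pdist_families <- function(seq, lengths) {
  n <- nrow(seq)
  G <- length(lengths)
  fam <- rep.int(seq_len(G), lengths)
  pairs <- combn(n, 2L)
  P <- ncol(pairs)
  p <- matrix(0, P, G)
  for (k in seq_len(P)) {
    z <- seq[pairs[1L, k], ] != seq[pairs[2L, k], ]
    p[k, ] <- rowsum(as.numeric(z), fam) / lengths
  }
  list(pairs = pairs, p = p, taxa = rownames(seq))
}

# assemble a square distance matrix from a pair vector
.square_from_pairs <- function(vals, pairs, taxa_names) {
  n <- length(taxa_names)
  m <- matrix(0, n, n, dimnames = list(taxa_names, taxa_names))
  for (k in seq_len(ncol(pairs))) {
    m[pairs[1L, k], pairs[2L, k]] <- m[pairs[2L, k], pairs[1L, k]] <- vals[k]
  }
  m
}

# ---- neighbor joining -------------------------------------------------------

# agglomeration core; returns the newick string plus (optionally) the split
# masks of every internal cluster on a sorted reference taxon ordering
.nj_core <- function(d, labels, ref = NULL) {
  m <- nrow(d)
  if (m < 3L) abort("neighbor joining requires at least 3 taxa")
  lab <- labels
  subtree <- lab
  use_mask <- !is.null(ref)
  masks <- if (use_mask) vapply(lab, .mask_of, integer(1), ref = ref) else integer(m)
  out_masks <- integer(0)
  active <- seq_len(m)
  D <- d

  fmt <- function(x) sprintf("%.6f", max(x, 0))
  while (length(active) > 3L) {
    na <- length(active)
    r <- rowSums(D[active, active, drop = FALSE])
    best_i <- best_j <- 0L; best_q <- Inf
    for (ii in seq_len(na - 1L)) {
      for (jj in (ii + 1L):na) {
        q <- (na - 2) * D[active[ii], active[jj]] - r[ii] - r[jj]
        if (q < best_q) { best_q <- q; best_i <- ii; best_j <- jj }
      }
    }
    i <- active[best_i]; j <- active[best_j]
    dij <- D[i, j]
    li <- dij / 2 + (r[best_i] - r[best_j]) / (2 * (na - 2))
    lj <- dij - li
    if (li < 0) { lj <- dij; li <- 0 }
    if (lj < 0) { li <- dij; lj <- 0 }
    # extend matrix with the new node
    newd <- (D[i, active] + D[j, active] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, active] <- newd; D[active, u] <- newd; D[u, u] <- 0
    subtree <- c(subtree, paste0("(", subtree[i], ":", fmt(li), ",",
                                 subtree[j], ":", fmt(lj), ")"))
    if (use_mask) {
      mu <- bitwOr(masks[i], masks[j])
      masks <- c(masks, mu)
      out_masks <- c(out_masks, mu)
    } else masks <- c(masks, 0L)
    active <- c(setdiff(active, c(i, j)), u)
    active <- sort(active)
  }
  a <- active
  l1 <- (D[a[1], a[2]] + D[a[1], a[3]] - D[a[2], a[3]]) / 2
  l2 <- D[a[1], a[2]] - l1
  l3 <- D[a[1], a[3]] - l1
  nwk <- paste0("(", subtree[a[1]], ":", fmt(l1), ",", subtree[a[2]], ":",
                fmt(l2), ",", subtree[a[3]], ":", fmt(l3), ");")
  list(newick = nwk, masks = out_masks)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with two deterministic conventions:
#' ties in the Q criterion are broken by the smallest `(row, column)` index
#' pair under the input taxon ordering, and a negative estimated branch
#' length is clamped to zero with the deficit shifted to the adjacent
#' (sister) branch so the pair's summed length is preserved. The output is
#' unrooted.
#'
#' @param D A `protein_dist` object, a `dist`, or a square symmetric matrix
#'   with taxon dimnames (corrected distances).
#' @return A `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "protein_dist")) { labels <- D$taxa; d <- D$d }
  else if (inherits(D, "dist")) { d <- as.matrix(D); labels <- rownames(d) }
  else { d <- as.matrix(D); labels <- rownames(d) }
  if (is.null(labels)) abort("distance matrix must carry taxon names")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  res <- .nj_core(d, labels)
  parse_newick(res$newick)
}
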