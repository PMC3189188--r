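# ---- experiment configuration ----------------------------------------------

#' Configuration of a highway-of-gene-sharing simulation experiment
#'
#' Bundles the species tree, the designated donor and recipient lineages, and
#' the simulation parameters: focal internal branch length `b`
#' (substitutions/site), gene count `G`, gene length `L` (residues), HGT
#' fraction `h` (the fraction of gene families whose recipient ortholog is
#' replaced by the donor copy), and replicate count `R`.
#'
#' @param b Focal internal branch length (substitutions per site).
#' @param species_tree Species tree with donor and recipient among its
#'   leaves; defaults to [default_species_tree()] at branch length `b`.
#' @param donor,recipient Donor / recipient leaf labels.
#' @param genes Number of gene families `G`.
#' @param len Gene length `L` in residues.
#' @param hgt HGT fraction `h` in `[0, 1]`.
#' @param replicates Number of replicates `R`.
#' @param seed Master RNG seed (integer).
#' @param model A [substitution_model()]; default plain JTT.
#' @param methods Reconstruction methods for sweeps.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(b = 0.05, species_tree = default_species_tree(b),
                              donor = "Bp", recipient = "F",
                              genes = 100L, len = 300L, hgt = 0,
                              replicates = 100L, seed = 1L,
                              model = substitution_model("JTT"),
                              methods = c("supermatrix-NJ", "quartet-supertree")) {
  if (hgt < 0 || hgt > 1) abort("hgt fraction must lie in [0, 1]")
  if (genes < 1 || len < 1 || replicates < 1) abort("genes, len, replicates must be >= 1")
  tips <- species_tree$tip.label
  if (!all(c(donor, recipient) %in% tips)) abort("donor and recipient must be leaves of the species tree")
  if (donor == recipient) abort("donor and recipient must differ")
  structure(
    list(b = b, species_tree = species_tree, donor = donor,
         recipient = recipient, genes = as.integer(genes), len = as.integer(len),
         hgt = hgt, replicates = as.integer(replicates), seed = as.integer(seed),
         model = model, methods = methods),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config> b =", x$b, "| G =", x$genes, "x", x$len, "aa | h =",
      x$hgt, "| R =", x$replicates, "| seed =", x$seed, "\n")
  cat("  highway:", x$donor, "->", x$recipient, "\n")
  invisible(x)
}

#' Default 7-taxon species tree with a donor lineage
#'
#' The unrooted tree `((A,(B,Bp)),C,(D,(E,F)))` used by the simulation
#' experiments: donor `Bp` sits sister to `B`, recipient `F` pairs with `E`,
#' and the internal branch subtending the `(E,F)` cherry has length `b` --
#' the branch whose recovery the experiment probes. All other branches take
#' `other_length` (default 0.1 substitutions/site). The "correct tree" used
#' for recovery scoring is this tree restricted to `A..F` (the donor is
#' excluded from reconstruction).
#'
#' @param b Focal internal branch length, `> 0`.
#' @param other_length Length of every other branch.
#' @return A `phylo` object.
#' @examples
#' tr <- default_species_tree(0.05)
#' @export
default_species_tree <- function(b, other_length = 0.1) {
  if (b <= 0) abort("focal branch length b must be > 0")
  o <- other_length
  txt <- sprintf(
    "((A:%1$g,(B:%1$g,Bp:%1$g):%1$g):%1$g,C:%1$g,(D:%1$g,(E:%1$g,F:%1$g):%2$g):%1$g);",
    o, b
  )
  parse_newick(txt)
}

# ---- genome sets ------------------------------------------------------------

.new_genome_set <- function(seq, lengths, alphabet, tree = NULL,
                            transfers = NULL) {
  G <- length(lengths)
  ids <- sprintf("fam_%04d", seq_len(G))
  if (is.null(transfers)) {
    transfers <- tibble(family = character(0), taxon = character(0),
                        donor = character(0))
  }
  structure(
    list(taxa = rownames(seq), seq = seq, lengths = setNames(lengths, ids),
         family_ids = ids, alphabet = alphabet, tree = tree,
         transfers = transfers),
    class = "genome_set"
  )
}

#' @export
print.genome_set <- function(x, ...) {
  cat("<genome_set>", length(x$taxa), "taxa x", length(x$family_ids),
      "families (", sum(x$lengths), "total columns ),",
      nrow(x$transfers), "transferred\n")
  invisible(x)
}

#' Number of gene families in a genome set
#' @param gs A `genome_set`.
#' @return Integer.
#' @export
n_families <- function(gs) length(gs$family_ids)

# half-open 0-based column ranges per family
.family_ranges <- function(gs) {
  ends <- cumsum(gs$lengths)
  starts <- c(0L, head(ends, -1L))
  tibble(family = gs$family_ids, start = unname(starts), end = unname(ends))
}

#' Extract one family alignment as a character matrix
#' @param gs A `genome_set`.
#' @param family Family index or id.
#' @return Character matrix (taxa x sites) of residues.
#' @export
family_alignment <- function(gs, family) {
  i <- if (is.character(family)) match(family, gs$family_ids) else as.integer(family)
  if (is.na(i) || i < 1L || i > n_families(gs)) abort("unknown family")
  ends <- cumsum(gs$lengths)
  cols <- (ends[i] - gs$lengths[i] + 1L):ends[i]
  m <- gs$seq[, cols, drop = FALSE]
  out <- matrix(gs$alphabet[m], nrow = nrow(m), dimnames = list(rownames(m), NULL))
  out
}

#' Per-family, per-taxon provenance flags
#' @param gs A `genome_set`.
#' @return Tibble (family, taxon, provenance) with provenance in
#'   `c("vertical", "transferred")`.
#' @export
provenance <- function(gs) {
  full <- tidyr::expand_grid(family = gs$family_ids, taxon = gs$taxa)
  tr <- dplyr::mutate(gs$transfers[c("family", "taxon")], provenance = "transferred")
  out <- dplyr::left_join(full, tr, by = c("family", "taxon"))
  out$provenance[is.na(out$provenance)] <- "vertical"
  out
}

# ---- sequence evolution -----------------------------------------------------

# integer-coded simulation core: states 1..S down the tree, one matrix pass
# per edge, transition matrices cached per (length, rate)
.evolve_int <- function(tree, L, model, site_rates = NULL) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("all branch lengths must be present for simulation")
  }
  S <- length(model$alphabet)
  n <- ape::Ntip(tree)
  nnode <- n + tree$Nnode
  if (is.null(site_rates)) {
    site_rates <- rep(1, L)
    if (length(model$rates) > 1L || model$p_inv > 0) {
      cat_idx <- sample.int(length(model$rates), L, replace = TRUE,
                            prob = model$rate_weights)
      site_rates <- model$rates[cat_idx]
      if (model$p_inv > 0) {
        site_rates[runif(L) < model$p_inv] <- 0
      }
    }
  }
  ucats <- sort(unique(site_rates))
  states <- matrix(0L, nnode, L)
  root <- n + 1L
  states[root, ] <- sample.int(S, L, replace = TRUE, prob = model$freqs)
  tr <- ape::reorder.phylo(tree, "cladewise")
  pcache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    len <- tr$edge.length[i]
    ps <- states[p, ]
    cs <- integer(L)
    for (r in ucats) {
      sel <- site_rates == r
      if (!any(sel)) next
      if (r == 0) { cs[sel] <- ps[sel]; next }
      key <- paste0(format(len, digits = 12), "@", format(r, digits = 12))
      P <- pcache[[key]]
      if (is.null(P)) {
        P <- prob_matrix(model, len, rate = r)
        pcache[[key]] <- P
      }
      pssel <- ps[sel]
      idx <- which(sel)
      for (a in unique(pssel)) {
        ia <- idx[pssel == a]
        cs[ia] <- sample.int(S, length(ia), replace = TRUE, prob = P[a, ])
      }
    }
    states[ch, ] <- cs
  }
  out <- states[seq_len(n), , drop = FALSE]
  rownames(out) <- tr$tip.label
  out[order(rownames(out)), , drop = FALSE]
}

#' Simulate one gene-family alignment along a tree
#'
#' Draws the root sequence from the model's equilibrium frequencies and
#' evolves each site independently down the tree with transition
#' probabilities `exp(Qt)` per branch; no indels, so the output is a gapless
#' positional alignment with one row per leaf.
#'
#' @param tree A `phylo` with all branch lengths set.
#' @param L Alignment length (sites), `>= 1`.
#' @param model A [substitution_model()].
#' @return Character matrix (taxa x `L`) of residues.
#' @export
evolve_alignment <- function(tree, L, model = substitution_model("JTT")) {
  if (L < 1) abort("alignment length must be >= 1")
  m <- .evolve_int(tree, as.integer(L), model)
  matrix(model$alphabet[m], nrow = nrow(m), dimnames = list(rownames(m), NULL))
}

#' Simulate a genome set of orthologous gene families
#'
#' Simulates `config$genes` independent single-copy families, each of
#' `config$len` residues, along the configured species tree. All provenance
#' flags start as `"vertical"`; apply the highway with [apply_highway()].
#'
#' @param config An [experiment_config()].
#' @return A `genome_set`.
#' @export
simulate_genome_set <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  total <- config$genes * config$len
  seq <- .evolve_int(config$species_tree, total, config$model)
  .new_genome_set(seq, rep(config$len, config$genes),
                  config$model$alphabet, tree = config$species_tree)
}

#' Impose a directed highway of gene sharing by ortholog replacement
#'
#' Chooses `round(G * h)` families uniformly at random without replacement
#' and, in each, overwrites the recipient's sequence with the donor's
#' sequence from the same family (instantaneous replacement at the tips).
#' The donor row is unchanged; affected families are flagged
#' `"transferred"` for the recipient.
#'
#' @param gs A `genome_set`.
#' @param donor,recipient Taxon labels in `gs`.
#' @param h HGT fraction in `[0, 1]`.
#' @return The modified `genome_set`.
#' @export
apply_highway <- function(gs, donor, recipient, h) {
  if (h < 0 || h > 1) abort("hgt fraction must lie in [0, 1]")
  if (!all(c(donor, recipient) %in% gs$taxa)) abort("donor and recipient must be in the genome set")
  G <- n_families(gs)
  k <- round(G * h)
  if (k == 0L) return(gs)
  fams <- sort(sample.int(G, k))
  ends <- cumsum(gs$lengths)
  starts <- ends - gs$lengths + 1L
  for (i in fams) {
    cols <- starts[i]:ends[i]
    gs$seq[recipient, cols] <- gs$seq[donor, cols]
  }
  gs$transfers <- dplyr::bind_rows(
    gs$transfers,
    tibble(family = gs$family_ids[fams], taxon = recipient, donor = donor)
  )
  gs
}

#' Remove one taxon from every family of a genome set
#'
#' @param gs A `genome_set`.
#' @param taxon Taxon label to drop.
#' @return The reduced `genome_set`.
#' @export
drop_taxon <- function(gs, taxon) {
  if (!taxon %in% gs$taxa) abort(paste0("taxon not in genome set: ", taxon))
  gs$seq <- gs$seq[setdiff(rownames(gs$seq), taxon), , drop = FALSE]
  gs$taxa <- rownames(gs$seq)
  gs$transfers <- gs$transfers[gs$transfers$taxon != taxon, , drop = FALSE]
  gs
}
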