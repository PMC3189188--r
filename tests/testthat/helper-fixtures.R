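# shared fixture builders for the test suite

# additive distance matrix implied by a tree's path lengths
tree_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

# quick alignment fixture: n taxa, constant columns except where stated
toy_alignment <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# small taxonomy covering the synthetic screen fixtures
toy_taxonomy <- function() {
  as_taxonomy(tibble::tibble(
    taxon = c("A", "B", "C", "D", "E", "F", "G", "H"),
    genus = paste0("g", 1:8),
    order = c("Ord1", "Ord1", "Ord1", "Ord1", "Ord2", "Ord2", "Ord3", "Ord3"),
    domain = c(rep("Bacteria", 6), rep("Archaea", 2))
  ))
}

# plurality map derived from a single tree, unit margins
pmap_of_tree <- function(tree) {
  plurality_quartet_map(embedded_quartet_tally(list(tree)))
}

# deterministic per-test RNG scope
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
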