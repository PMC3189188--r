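# brute-force oracle for displaced-leaf detection: smallest set of leaves
# (size 1 or 2) whose removal reconciles gene tree and restricted scaffold
prune_oracle <- function(scaffold, gene_tree) {
  shared <- intersect(scaffold$tip.label, gene_tree$tip.label)
  rs <- restrict_to_taxa(scaffold, shared)
  if (robinson_foulds(rs, restrict_to_taxa(gene_tree, shared)) == 0L) {
    return(character(0))
  }
  for (k in 1:2) {
    combos <- combn(sort(shared), k)
    hits <- list()
    for (j in seq_len(ncol(combos))) {
      keep <- setdiff(shared, combos[, j])
      if (length(keep) < 4) next
      if (same_topology(restrict_to_taxa(rs, keep),
                        restrict_to_taxa(gene_tree, keep))) {
        hits[[length(hits) + 1L]] <- combos[, j]
      }
    }
    if (length(hits)) return(hits)
  }
  NULL
}

scaffold6 <- function() {
  root_on_outgroup(parse_newick(
    "((A:0.1,B:0.1):0.1,C:0.1,(D:0.1,(E:0.1,F:0.1):0.1):0.1);"), "A")
}

test_that("scaffold from one clean partition equals that family's rooted NJ tree", {
  cfg <- experiment_config(b = 0.05, genes = 1, len = 1500, seed = 61)
  with_seed(61, gs <- simulate_genome_set(cfg))
  aln <- family_alignment(gs, 1)
  sc <- build_scaffold(list(p1 = aln), root_outgroup = "C")
  expect_true(ape::is.rooted(sc))
  nj <- neighbor_joining(protein_distance_matrix(aln))
  expect_equal(robinson_foulds(ape::unroot(sc), nj), 0L)
})

test_that("equal-length partitions on one underlying tree reproduce its topology", {
  cfg <- experiment_config(b = 0.05, genes = 4, len = 700, seed = 62)
  with_seed(62, gs <- simulate_genome_set(cfg))
  parts <- lapply(1:4, function(i) family_alignment(gs, i))
  names(parts) <- paste0("p", 1:4)
  sc <- build_scaffold(parts, root_outgroup = "C")
  truth <- default_species_tree(0.05)
  expect_equal(robinson_foulds(ape::unroot(sc), truth), 0L)
})

test_that("mixed protein and nucleotide partitions combine by weighted distance", {
  # nucleotide partition simulated under K2P on the same tree
  cfg <- experiment_config(b = 0.05, genes = 1, len = 900, seed = 63)
  with_seed(63, gs <- simulate_genome_set(cfg))
  prot <- family_alignment(gs, 1)
  with_seed(64, nuc <- evolve_alignment(default_species_tree(0.05), 900,
                                        substitution_model("K2P")))
  sc <- build_scaffold(list(p1 = prot, p2 = nuc), root_outgroup = "C")
  expect_equal(robinson_foulds(ape::unroot(sc), default_species_tree(0.05)), 0L)
})

test_that("rooting requires a separable outgroup", {
  tr <- parse_newick("((A,B),C,(D,(E,F)));")
  rooted <- root_on_outgroup(tr, c("A", "B"))
  expect_true(ape::is.rooted(rooted))
  expect_error(root_on_outgroup(tr, c("A", "D")), "not separable")
  expect_error(root_on_outgroup(tr, character(0)), "non-empty")
  # single-taxon outgroup: root on its pendant edge
  r1 <- root_on_outgroup(tr, "C")
  kids <- r1$edge[r1$edge[, 1] == ape::Ntip(r1) + 1L, 2]
  expect_true(which(r1$tip.label == "C") %in% kids)
})

test_that("a gene tree matching the scaffold yields no reticulation candidates", {
  sc <- scaffold6()
  gene <- parse_newick("((A,B),C,(D,(E,F)));")
  cands <- detect_reticulations(sc, gene, s = 0.9, family = "f1")
  expect_equal(nrow(cands), 0L)
  # fewer than 4 shared taxa: skipped with a reason
  small <- parse_newick("((A,B),C);")
  out <- detect_reticulations(sc, small, s = 0.9)
  expect_equal(nrow(out), 0L)
  expect_match(attr(out, "skipped"), "4 shared")
  expect_error(detect_reticulations(sc, parse_newick("((A,Z),(C,D));"), 0.9),
               "absent from scaffold")
})

test_that("an F-beside-B gene tree yields a single moved={F} candidate", {
  sc <- scaffold6()
  gene <- parse_newick("((A,(B,F)0.99)0.99,C,(D,E)0.99);")
  cands <- detect_reticulations(sc, gene, s = 0.9, family = "f1")
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$moved[[1]], "F")
  edges <- scaffold_edges(sc)
  src_clade <- edges$clade[[match(cands$source_edge, edges$edge_id)]]
  tgt_clade <- edges$clade[[match(cands$target_edge, edges$edge_id)]]
  # source on the B lineage, target at F's scaffold position
  expect_true("B" %in% src_clade)
  expect_equal(tgt_clade, "F")
  # support gate: the same gene tree with weak supports is discarded
  weak <- parse_newick("((A,(B,F)0.5)0.5,C,(D,E)0.5);")
  expect_equal(nrow(detect_reticulations(sc, weak, s = 0.9)), 0L)
})

test_that("displaced leaves match a brute-force prune oracle on constructed cases", {
  with_seed(83, {
    checked <- 0L
    for (i in 1:30) {
      if (checked >= 8L) break
      base <- random_tree(7, LETTERS[1:7])
      gene <- base
      if (i %% 2 == 0) {
        # regraft one leaf onto a random edge elsewhere
        leaf <- sample(gene$tip.label, 1)
        pruned <- ape::drop.tip(gene, leaf)
        e <- sample(nrow(pruned$edge), 1)
        gene <- phytools::bind.tip(pruned, leaf, edge.length = 0.1,
                                   where = pruned$edge[e, 2], position = 0.01)
      } else {
        # swap two leaf labels
        sw <- sample(seq_along(gene$tip.label), 2)
        gene$tip.label[sw] <- gene$tip.label[rev(sw)]
      }
      sc <- root_on_outgroup(base, sort(base$tip.label)[1])
      oracle <- prune_oracle(sc, gene)
      if (is.null(oracle) || !length(oracle)) next  # unchanged topology
      checked <- checked + 1L
      cands <- detect_reticulations(sc, gene, s = 0)
      moved <- sort(unlist(cands$moved))
      # the detected displacement set must be one of the oracle's minimal sets
      keys <- vapply(oracle, paste, character(1), collapse = ",")
      expect_true(paste(moved, collapse = ",") %in% keys)
    }
    expect_gte(checked, 5L)
  })
})

test_that("assemble_network merges evidence and applies the family threshold", {
  sc <- scaffold6()
  gene <- parse_newick("((A,(B,F)0.99)0.99,C,(D,E)0.99);")
  cands <- dplyr::bind_rows(lapply(sprintf("fam_%02d", 1:48), function(f)
    detect_reticulations(sc, gene, s = 0.9, family = f)))
  net <- assemble_network(sc, cands, min_family_support = 5)
  expect_equal(nrow(net$reticulations), 1L)
  expect_equal(net$reticulations$n_families, 48L)
  expect_length(net$reticulations$families[[1]], 48L)

  few <- dplyr::bind_rows(lapply(sprintf("fam_%02d", 1:3), function(f)
    detect_reticulations(sc, gene, s = 0.9, family = f)))
  net2 <- assemble_network(sc, few, min_family_support = 5)
  expect_equal(nrow(net2$reticulations), 0L)
  expect_equal(nrow(net2$dropped), 1L)

  net3 <- assemble_network(sc, NULL)
  expect_equal(nrow(net3$reticulations), 0L)
})

test_that("deleting all reticulations from the network yields the scaffold", {
  sc <- scaffold6()
  gene <- parse_newick("((A,(B,F)0.99)0.99,C,(D,E)0.99);")
  cands <- dplyr::bind_rows(lapply(paste0("f", 1:6), function(f)
    detect_reticulations(sc, gene, s = 0.9, family = f)))
  net <- assemble_network(sc, cands)
  out <- write_network(net)
  tree_rows <- out$edges[out$edges$kind == "tree", ]
  expect_equal(nrow(tree_rows), nrow(sc$edge))
  expect_identical(write_newick(net$scaffold), write_newick(sc))
  # extended newick carries exactly one reticulation label, used twice
  expect_equal(lengths(regmatches(out$newick, gregexpr("#H1", out$newick))), 2L)
  expect_false(grepl("#H2", out$newick))
})

test_that("write/read round-trips the network through the edge-list TSV", {
  sc0 <- parse_newick("((A:0.1,B:0.1):0.1,C:0.1,(D:0.1,(E:0.1,F:0.1):0.1):0.1);")
  sc <- parse_newick(write_newick(root_on_outgroup(sc0, "A")))
  gene <- parse_newick("((A,(B,F)0.99)0.99,C,(D,E)0.99);")
  cands <- dplyr::bind_rows(lapply(paste0("f", 1:6), function(f)
    detect_reticulations(sc, gene, s = 0.9, family = f)))
  net <- assemble_network(sc, cands)
  tmp <- file.path(withr::local_tempdir(), "net")
  write_network(net, tmp)
  back <- read_network(paste0(tmp, ".tsv"))
  expect_identical(write_newick(back$scaffold), write_newick(net$scaffold))
  expect_equal(back$reticulations$source_edge, net$reticulations$source_edge)
  expect_equal(back$reticulations$target_edge, net$reticulations$target_edge)
  expect_equal(back$reticulations$moved, net$reticulations$moved)
  # second round trip is exact
  out1 <- write_network(net)
  out2 <- write_network(back)
  expect_identical(out2$edges[c("parent", "child", "kind", "moved")],
                   out1$edges[c("parent", "child", "kind", "moved")])
})

test_that("clean simulated families yield no reticulations at high support", {
  cfg <- experiment_config(b = 0.05, genes = 6, len = 1200, seed = 85)
  with_seed(85, gs <- simulate_genome_set(cfg))
  gs <- drop_taxon(gs, "Bp")
  gts <- gene_tree_set(gs)
  gts <- lapply(gts, function(t) { t$node.label <- rep("1.0", t$Nnode); t })
  sc <- build_scaffold(list(p = concatenate_supermatrix(gs)$aln),
                       root_outgroup = "A")
  cands <- dplyr::bind_rows(lapply(names(gts), function(nm)
    detect_reticulations(sc, gts[[nm]], s = 0.95, family = nm)))
  net <- assemble_network(sc, cands, min_family_support = 2)
  expect_equal(nrow(net$reticulations), 0L)
})

test_that("a simulated highway produces a moved={F} reticulation from the B lineage", {
  cfg <- experiment_config(b = 0.05, genes = 40, len = 300, seed = 86)
  with_seed(86, gs <- simulate_genome_set(cfg))
  with_seed(87, gs <- apply_highway(gs, "Bp", "F", 0.45))
  gs <- drop_taxon(gs, "Bp")
  gts <- gene_tree_set(gs)
  gts <- lapply(gts, function(t) { t$node.label <- rep("1.0", t$Nnode); t })
  # scaffold: the true species history (what ribosomal genes would give)
  sc <- parse_newick(write_newick(root_on_outgroup(
    restrict_to_taxa(default_species_tree(0.05), gs$taxa), "A")))
  cands <- dplyr::bind_rows(lapply(names(gts), function(nm)
    detect_reticulations(sc, gts[[nm]], s = 0.95, family = nm)))
  net <- assemble_network(sc, cands, min_family_support = 5)
  expect_gt(nrow(net$reticulations), 0L)
  moved_f <- vapply(net$reticulations$moved, identical, logical(1), y = "F")
  expect_true(any(moved_f))
  main <- net$reticulations[moved_f, ]
  main <- main[which.max(main$n_families), ]
  edges <- scaffold_edges(sc)
  src_clade <- edges$clade[[match(main$source_edge, edges$edge_id)]]
  expect_true("B" %in% src_clade)
  expect_gte(main$n_families, 5L)
})
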