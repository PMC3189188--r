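# gene trees with controlled support values for screen fixtures
supported_tree <- function(nwk) parse_newick(nwk)

test_that("supported_bipartitions filters by normalised threshold", {
  tr <- parse_newick("(((A,B)0.95,(C,D)0.60)0.99,E,F);")
  expect_equal(nrow(supported_bipartitions(tr, 0)), 3L)
  expect_equal(nrow(supported_bipartitions(tr, 0.9)), 2L)
  expect_equal(nrow(supported_bipartitions(tr, 0.97)), 1L)
  # 0-100 scale thresholds and supports both accepted
  tr100 <- parse_newick("(((A,B)95,(C,D)60)99,E,F);")
  expect_equal(nrow(supported_bipartitions(tr100, 90)), 2L)
  expect_error(supported_bipartitions(parse_newick("((A,B),(C,D),(E,F));"), 0.5),
               "no support")
})

test_that("a tree never conflicts with itself; supported conflicts are found", {
  t1 <- supported_tree("(((A,B)0.99,(C,D)0.99)0.99,(E,F));")
  rep_self <- screen_conflicts(list(g1 = t1, g2 = t1), 0.9, toy_taxonomy())
  expect_equal(nrow(rep_self), 0L)

  # displace C next to A with high support
  t2 <- supported_tree("(((A,C)0.98,(B,D)0.98)0.99,(E,F));")
  rep2 <- screen_conflicts(list(g1 = t1, g2 = t2), 0.9, toy_taxonomy())
  expect_gt(nrow(rep2), 0L)
  expect_true(all(rep2$support_1 >= 0.9 & rep2$support_2 >= 0.9))
  # every reported pair really is incompatible
  for (i in seq_len(nrow(rep2))) {
    p1 <- strsplit(rep2$bipartition_1[i], "|", fixed = TRUE)[[1]]
    p2 <- strsplit(rep2$bipartition_2[i], "|", fixed = TRUE)[[1]]
    b1 <- bipartition(strsplit(p1[1], ",")[[1]], strsplit(p1[2], ",")[[1]])
    b2 <- bipartition(strsplit(p2[1], ",")[[1]], strsplit(p2[2], ",")[[1]])
    expect_false(are_compatible(b1, b2))
  }

  # same displacement below threshold: silent
  t2lo <- supported_tree("(((A,C)0.50,(B,D)0.50)0.99,(E,F));")
  expect_equal(nrow(screen_conflicts(list(g1 = t1, g2 = t2lo), 0.9,
                                     toy_taxonomy())), 0L)
})

test_that("conflict counts are monotone non-increasing in the support threshold", {
  t1 <- supported_tree("(((A,B)0.99,(C,D)0.85)0.95,(E,F));")
  t2 <- supported_tree("(((A,C)0.92,(B,D)0.80)0.95,(E,F));")
  taxo <- toy_taxonomy()
  counts <- vapply(c(0, 0.5, 0.8, 0.9, 0.95, 1),
                   function(s) nrow(screen_conflicts(list(a = t1, b = t2), s, taxo)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the report is invariant to the order of the input trees", {
  t1 <- supported_tree("(((A,B)0.99,(C,D)0.99)0.99,(E,F));")
  t2 <- supported_tree("(((A,C)0.98,(B,D)0.98)0.99,(E,F));")
  t3 <- supported_tree("(((A,B)0.97,(C,E)0.97)0.99,(D,F));")
  taxo <- toy_taxonomy()
  r1 <- screen_conflicts(list(g1 = t1, g2 = t2, g3 = t3), 0.9, taxo)
  r2 <- screen_conflicts(list(g3 = t3, g1 = t1, g2 = t2), 0.9, taxo)
  key <- function(r) {
    k <- apply(tibble::as_tibble(r), 1, paste, collapse = "\r")
    sort(paste(pmin(r$tree_1, r$tree_2), pmax(r$tree_1, r$tree_2),
               pmin(r$bipartition_1, r$bipartition_2),
               pmax(r$bipartition_1, r$bipartition_2), r$rank))
  }
  expect_equal(key(r1), key(r2))
})

test_that("conflicts are rank-classified by the displaced taxon's new neighbours", {
  taxo <- toy_taxonomy()  # A-D Ord1, E-F Ord2 (Bacteria); G-H Ord3 (Archaea)
  # intra-order: B moves among other Ord1 taxa
  b1 <- bipartition(c("A", "B"), c("C", "D"))
  b2 <- bipartition(c("A", "C"), c("B", "D"))
  expect_equal(classify_conflict_rank(b1, b2, taxo), "intra-order")
  # inter-order: E (Ord2) claimed inside an Ord1 group
  b3 <- bipartition(c("A", "B", "E"), c("C", "D", "F"))
  b4 <- bipartition(c("A", "B", "F"), c("C", "D", "E"))
  expect_equal(classify_conflict_rank(b3, b4, taxo), "inter-order")
  # inter-domain: G (Archaea) moved beside Bacteria
  b5 <- bipartition(c("G", "H"), c("A", "B", "C"))
  b6 <- bipartition(c("A", "G"), c("B", "C", "H"))
  expect_equal(classify_conflict_rank(b5, b6, taxo), "inter-domain")
  expect_error(classify_conflict_rank(
    bipartition(c("A", "Z"), c("B", "C")),
    bipartition(c("A", "B"), c("Z", "C")), taxo), "missing from taxonomy")
})

test_that("filter_partitions gap-masks only offending taxa at or above the cut", {
  t1 <- supported_tree("(((A,B)0.99,(C,D)0.99)0.99,(E,F));")
  t2 <- supported_tree("(((A,E)0.98,(B,C)0.98)0.99,(D,F));")  # E displaced into Ord1
  taxo <- toy_taxonomy()
  rep2 <- screen_conflicts(list(p1 = t1, p2 = t2), 0.9, taxo)
  expect_true(any(rep2$rank == "inter-order"))

  parts <- list(
    p1 = toy_alignment(c(A = "AAAA", B = "AAAA", C = "AAAA", D = "AAAA",
                         E = "AAAA", F = "AAAA")),
    p2 = toy_alignment(c(A = "RRRR", B = "RRRR", C = "RRRR", D = "RRRR",
                         E = "RRRR", F = "RRRR"))
  )
  res <- filter_partitions(parts, rep2)
  expect_gt(nrow(res$exclusions), 0L)
  masked <- unique(res$exclusions$taxon)
  for (tx in masked) {
    expect_true(all(res$partitions$p2[tx, ] == "-"))
  }
  # untouched taxa keep their residues; column counts preserved
  expect_equal(ncol(res$partitions$p1), 4L)
  keep <- setdiff(rownames(parts$p1), masked)
  expect_identical(res$partitions$p1[keep, ], parts$p1[keep, ])

  # empty report leaves everything alone
  empty <- screen_conflicts(list(p1 = t1, p2 = t1), 0.9, taxo)
  expect_identical(filter_partitions(parts, empty)$partitions, parts)

  # intra-order-only conflicts are preserved under the default configuration
  t3 <- supported_tree("(((A,C)0.98,(B,D)0.98)0.99,(E,F));")
  rep3 <- screen_conflicts(list(p1 = t1, p2 = t3), 0.9, taxo)
  expect_true(all(rep3$rank == "intra-order"))
  expect_identical(filter_partitions(parts, rep3)$partitions, parts)
})

test_that("bootstrap-style replicate trees of clean data raise no conflicts", {
  # replicate gene trees from one clean simulation, supports set to 1
  cfg <- experiment_config(b = 0.05, genes = 8, len = 800, seed = 91)
  with_seed(91, gs <- simulate_genome_set(cfg))
  gs <- drop_taxon(gs, "Bp")
  gts <- gene_tree_set(gs)
  gts <- lapply(gts, function(t) { t$node.label <- rep("1.0", t$Nnode); t })
  taxo <- as_taxonomy(tibble::tibble(
    taxon = gs$taxa, genus = paste0("g", seq_along(gs$taxa)),
    order = "Ord1", domain = "Bacteria"))
  rep <- screen_conflicts(gts, 0.95, taxo)
  # clean long alignments: the vast majority of pairs agree
  expect_lte(nrow(rep), 2L)
})
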