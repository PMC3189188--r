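# counting oracle: tally a quartet by explicit restriction of every tree
tally_oracle <- function(trees, q) {
  out <- c(0L, 0L, 0L, 0L)
  names(out) <- c("12|34", "13|24", "14|23", "U")
  qs <- sort(q)
  for (tr in trees) {
    if (!all(qs %in% tr$tip.label)) next
    top <- induced_quartet_topology(tr, qs)
    if (top == "unresolved") { out["U"] <- out["U"] + 1L; next }
    first_pair <- sort(strsplit(strsplit(top, "|", fixed = TRUE)[[1]][1], ",")[[1]])
    code <- if (setequal(first_pair, qs[c(1, 2)])) "12|34"
    else if (setequal(first_pair, qs[c(1, 3)])) "13|24"
    else "14|23"
    out[code] <- out[code] + 1L
  }
  out
}

test_that("a single resolved tree yields one weight-1 entry per subset", {
  tr <- parse_newick("((A,B),C,(D,(E,F)));")
  tly <- embedded_quartet_tally(list(tr))
  expect_equal(nrow(tly), choose(6, 4))
  w <- as.matrix(tly[, c("w12.34", "w13.24", "w14.23")])
  expect_true(all(rowSums(w) == 1))
  expect_true(all(tly$unresolved == 0))
  # doubling the input doubles every weight
  tly2 <- embedded_quartet_tally(list(tr, tr))
  expect_equal(as.matrix(tly2[, 5:8]), 2 * as.matrix(tly[, 5:8]))
})

test_that("mixed topologies are counted verbatim, matching the counting oracle", {
  t_true <- parse_newick("((A,B),C,(D,(E,F)));")
  t_hgt <- parse_newick("((A,(B,F)),C,(D,E));")
  trees <- c(replicate(11, t_true, simplify = FALSE),
             replicate(9, t_hgt, simplify = FALSE))
  tly <- embedded_quartet_tally(trees)
  for (i in c(1, 4, 8, 15)) {
    q <- c(tly$t1[i], tly$t2[i], tly$t3[i], tly$t4[i])
    expect_equal(unname(as.integer(tly[i, 5:8])),
                 unname(as.integer(tally_oracle(trees, q))))
  }
  # the A,B,E,F subset splits 11 to 9
  row <- which(tly$t1 == "A" & tly$t2 == "B" & tly$t3 == "E" & tly$t4 == "F")
  expect_equal(sort(as.integer(tly[row, 5:7]), decreasing = TRUE)[1:2], c(11L, 9L))
})

test_that("tallies tolerate overlapping but unequal taxon sets", {
  t1 <- parse_newick("((A,B),C,(D,E));")
  t2 <- parse_newick("((A,B),C,(D,F));")
  tly <- embedded_quartet_tally(list(t1, t2))
  expect_equal(nrow(tly), choose(6, 4))
  tot <- rowSums(as.matrix(tly[, 5:8]))
  # subsets fully inside one tree only get weight 1; cross-subsets 0
  expect_true(all(tot %in% c(0, 1, 2)))
  row_abcd <- which(tly$t1 == "A" & tly$t2 == "B" & tly$t3 == "C" & tly$t4 == "D")
  expect_equal(sum(tly[row_abcd, 5:8]), 2)
})

test_that("plurality takes the max-weight topology; exact ties are undecided", {
  t_true <- parse_newick("((A,B),C,(D,(E,F)));")
  t_hgt <- parse_newick("((A,(B,F)),C,(D,E));")
  tly <- embedded_quartet_tally(c(replicate(11, t_true, simplify = FALSE),
                                  replicate(9, t_hgt, simplify = FALSE)))
  pm <- plurality_quartet_map(tly)
  row <- which(pm$t1 == "A" & pm$t2 == "B" & pm$t3 == "E" & pm$t4 == "F")
  expect_equal(pm$margin[row], 2)
  expect_false(pm$undecided[row])

  tly_tie <- embedded_quartet_tally(c(replicate(5, t_true, simplify = FALSE),
                                      replicate(5, t_hgt, simplify = FALSE)))
  pm_tie <- plurality_quartet_map(tly_tie)
  row <- which(pm_tie$t1 == "A" & pm_tie$t2 == "B" & pm_tie$t3 == "E" &
                 pm_tie$t4 == "F")
  expect_true(pm_tie$undecided[row])
  expect_equal(pm_tie$margin[row], 0)
})

test_that("the supertree of one tree's quartets is that tree (self-consistency)", {
  with_seed(77, {
    for (n in 5:8) {
      tr <- random_tree(n, LETTERS[1:n])
      pm <- pmap_of_tree(tr)
      st <- supertree_search(pm, "exhaustive")
      expect_true(same_topology(st, tr))
      expect_equal(attr(st, "score"), choose(n, 4))
    }
  })
})

test_that("one conflicting minority quartet cannot overturn the exhaustive winner", {
  tr <- parse_newick("((A,B),C,(D,(E,F)));")
  tly <- embedded_quartet_tally(replicate(10, tr, simplify = FALSE))
  # inject a minority signal on one subset
  row <- which(tly$t1 == "C" & tly$t2 == "D" & tly$t3 == "E" & tly$t4 == "F")
  tly$w13.24[row] <- 4   # still below the 10 votes for the true pairing
  st <- supertree_search(plurality_quartet_map(tly), "exhaustive")
  expect_true(same_topology(st, tr))
})

test_that("a plurality dominated by F-beside-B placements moves F in the supertree", {
  t_hgt <- parse_newick("((A,(B,F)),C,(D,E));")
  t_true <- parse_newick("((A,B),C,(D,(E,F)));")
  tly <- embedded_quartet_tally(c(replicate(7, t_hgt, simplify = FALSE),
                                  replicate(3, t_true, simplify = FALSE)))
  st <- supertree_search(plurality_quartet_map(tly), "exhaustive")
  bp <- bipartitions(st)
  keys <- c(vapply(bp$side_a, paste, character(1), collapse = ","),
            vapply(bp$side_b, paste, character(1), collapse = ","))
  expect_true("B,F" %in% keys)
})

test_that("exhaustive scoring is invariant under taxon relabeling", {
  with_seed(78, {
    tr <- random_tree(6, LETTERS[1:6])
    t2 <- random_tree(6, LETTERS[1:6])
    pm <- plurality_quartet_map(embedded_quartet_tally(list(tr, tr, t2)))
    st <- supertree_search(pm, "exhaustive")
    perm <- setNames(letters[6:1], LETTERS[1:6])
    relab <- function(t) { t$tip.label <- unname(perm[t$tip.label]); t }
    pm2 <- plurality_quartet_map(embedded_quartet_tally(
      list(relab(tr), relab(tr), relab(t2))))
    st2 <- supertree_search(pm2, "exhaustive")
    expect_equal(attr(st2, "score"), attr(st, "score"))
    expect_true(same_topology(relab(st), st2))
  })
})

test_that("adding a gene tree equal to the supertree never changes the supertree", {
  with_seed(79, {
    trees <- replicate(5, random_tree(6, LETTERS[1:6]), simplify = FALSE)
    st <- supertree_search(plurality_quartet_map(embedded_quartet_tally(trees)),
                           "exhaustive")
    st2 <- supertree_search(plurality_quartet_map(embedded_quartet_tally(
      c(trees, list(st)))), "exhaustive")
    expect_true(same_topology(st, st2))
  })
})

test_that("greedy quartet joining equals exhaustive search on a random battery", {
  with_seed(80, {
    mism <- 0L
    for (i in 1:50) {
      n <- sample(6:7, 1)
      base <- random_tree(n, LETTERS[1:n])
      trees <- replicate(sample(4:9, 1), base, simplify = FALSE)
      # sprinkle conflicting trees to create realistic minority signal
      k <- sample(0:2, 1)
      if (k > 0) trees <- c(trees, replicate(k, random_tree(n, LETTERS[1:n]),
                                             simplify = FALSE))
      pm <- plurality_quartet_map(embedded_quartet_tally(trees))
      ex <- supertree_search(pm, "exhaustive")
      gr <- supertree_search(pm, "greedy")
      if (!same_topology(ex, gr)) mism <- mism + 1L
    }
    expect_equal(mism, 0L)
  })
})
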