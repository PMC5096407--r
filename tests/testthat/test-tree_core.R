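# Tree model, newick I/O, splits, consensus, RF, enumeration

test_that("newick parsing handles splits, stars and errors", {
  t1 <- parse_newick("((A,B),(C,D));")
  expect_equal(sort(t1$tip.label), c("A", "B", "C", "D"))
  expect_equal(length(bipartitions(t1)), 1L)
  expect_equal(bipartitions(t1), "C|D")  # side away from the reference taxon

  star <- parse_newick("(A,B,C,D);")
  expect_equal(length(bipartitions(star)), 0L)

  expect_error(parse_newick("((A,B),(C,D)"), class = "newick_parse_error")
  expect_error(parse_newick("(A,(B,C)));"), class = "newick_parse_error")
  err <- tryCatch(parse_newick("(A,(B,C)));"), error = identity)
  expect_false(is.na(err$offset))
})

test_that("newick round-trips random trees", {
  for (s in 1:5) {
    tr <- random_tree(7, seed = s)
    tr2 <- parse_newick(write_newick(tr))
    expect_equal(robinson_foulds(tr, tr2), 0L)
  }
})

test_that("bipartition count equals internal branch count", {
  for (s in 1:5) {
    n <- 4 + s
    tr <- random_tree(n, seed = 100 + s)
    # brute-force branch walk: an unrooted binary tree has n-3 internal edges
    expect_equal(length(bipartitions(tr)), n - 3L)
  }
  t5 <- parse_newick("(((A,B),C),(D,E));")
  expect_equal(length(bipartitions(t5)), 2L)
})

test_that("strict consensus keeps exactly the shared splits", {
  tr <- random_tree(8, seed = 1)
  expect_equal(robinson_foulds(strict_consensus(list(tr, tr, tr)), tr), 0L)

  a <- quartet("AB|CD")
  b <- quartet("AC|BD")
  expect_equal(length(bipartitions(strict_consensus(list(a, b)))), 0L)

  # oracle: ape::consensus(p = 1) on random tree sets
  for (s in 1:5) {
    trees <- lapply(1:4, function(i) random_tree(7, seed = 10 * s + i))
    mine <- strict_consensus(trees)
    apes <- ape::consensus(trees, p = 1, rooted = FALSE)
    expect_setequal(bipartitions(mine), bipartitions(apes))
  }
  t2 <- random_tree(6, seed = 2)
  expect_error(strict_consensus(list(random_tree(5, seed = 1), t2)),
               class = "leaf_set_error")
})

test_that("consensus is monotone: adding trees never adds splits", {
  trees <- lapply(1:5, function(i) random_tree(8, seed = 200 + i))
  for (k in 2:5) {
    prev <- bipartitions(strict_consensus(trees[seq_len(k - 1L)]))
    curr <- bipartitions(strict_consensus(trees[seq_len(k)]))
    expect_true(all(curr %in% prev))
  }
})

test_that("Robinson-Foulds distance is a symmetric-difference count", {
  tr <- random_tree(9, seed = 3)
  expect_equal(robinson_foulds(tr, tr), 0L)
  expect_equal(robinson_foulds(quartet("AB|CD"), quartet("AC|BD")), 2L)

  # exhaustive bound on all 5-leaf tree pairs: RF <= 2(n-3)
  all5 <- enumerate_topologies(LETTERS[1:5])
  for (i in seq_along(all5)) for (j in seq_along(all5))
    expect_lte(robinson_foulds(all5[[i]], all5[[j]]), 4L)

  # oracle: phangorn::RF.dist on random 8-leaf pairs
  skip_if_not_installed("phangorn")
  for (s in 1:6) {
    a <- random_tree(8, seed = 300 + s)
    b <- random_tree(8, seed = 400 + s)
    expect_equal(robinson_foulds(a, b), phangorn::RF.dist(a, b))
  }
})

test_that("topology enumeration matches the double factorial", {
  expect_equal(length(enumerate_topologies(LETTERS[1:4])), 3L)
  expect_equal(length(enumerate_topologies(paste0("t", 1:6))), 105L)
  expect_equal(length(enumerate_topologies(paste0("t", 1:8))), 10395L)
  expect_error(enumerate_topologies(paste0("t", 1:10)), class = "size_error")
  expect_error(enumerate_topologies(LETTERS[1:3]), class = "size_error")
})

test_that("enumeration is complete: random trees are members", {
  taxa <- paste0("t", 1:7)
  hashes <- hash_set(enumerate_topologies(taxa))
  expect_equal(length(unique(hashes)), 945L)
  for (s in 1:8) {
    tr <- random_tree(taxa, seed = 500 + s)
    expect_true(morphparsimony:::tree_hash(tr) %in% hashes)
  }
})

test_that("smallest rooted clade behaves on a known topology", {
  tr <- parse_newick("(O,(A,((B,C),(D,E))));")
  expect_setequal(smallest_clade(tr, "O", c("B", "D")), c("B", "C", "D", "E"))
  expect_setequal(smallest_clade(tr, "O", c("A", "B")),
                  c("A", "B", "C", "D", "E"))
})
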