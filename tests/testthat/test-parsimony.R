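# Fitch scoring, homoplasy diagnostics, implied weighting, collapse rule

test_that("Fitch steps match hand-checked quartets", {
  m <- cm(c("0", "0", "1", "1"))
  expect_equal(fitch_steps(m, quartet("AB|CD"), 1L), 1L)
  expect_equal(fitch_steps(m, quartet("AC|BD"), 1L), 2L)
  mc <- cm(c("1", "1", "1", "1"))
  expect_equal(fitch_steps(mc, quartet("AB|CD"), 1L), 0L)
  mall <- cm(c("?", "-", "?", "V"))
  expect_warning(s <- fitch_steps(mall, quartet("AB|CD"), 1L),
                 class = "uninformative_column_warning")
  expect_equal(s, 0L)
})

test_that("Fitch equals brute-force minimisation over ancestral states", {
  # every character of the published matrix restricted to a 6-taxon subset,
  # on a sample of topologies (the full 105-topology sweep runs in the
  # acceptance suite)
  m1 <- load_fixture("table1")
  sub <- subtaxa <- m1$taxa[c(1, 5, 9, 13, 20, 26)]
  msub <- morphparsimony:::subset_taxa(m1, sub)
  masks <- state_masks(msub)
  topos <- enumerate_topologies(msub$taxa)[c(1, 20, 50, 80, 105)]
  for (tr in topos) {
    idx <- match(tr$tip.label, msub$taxa)
    counts <- morphparsimony:::tree_counts(msub, tr)
    for (ch in seq_len(ncol(masks))) {
      expect_equal(counts[ch], brute_force_steps(tr, masks[idx, ch]),
                   info = paste("char", ch))
    }
  }
})

test_that("fitch agrees with phangorn on random binary matrices", {
  skip_if_not_installed("phangorn")
  for (s in 1:5) {
    tt <- random_tree(8, seed = 600 + s)
    sim <- simulate_matrix(tt, simulation_config(n_taxa = 8, n_chars = 30,
                                                 rate = 0.5), seed = s)
    m <- sim$matrix
    dat <- phangorn::phyDat(m$cells, type = "USER",
                            levels = c("0", "1"))
    expect_equal(tree_length(m, tt),
                 phangorn::parsimony(tt, dat, method = "fitch"))
  }
})

test_that("min and max steps follow the observed-state census", {
  m1 <- load_fixture("table1")
  expect_equal(min_steps(m1, 9L), 3L)   # states 0..3 observed
  mm <- cm(c("0", "0", "0", "0"))
  expect_equal(min_steps(mm, 1L), 0L)
  expect_equal(max_steps(mm, 1L), 0L)
  mb <- cm(c("0", "0", "1", "1"))
  expect_equal(min_steps(mb, 1L), 1L)
  m13 <- cm(rep(c("0", "1"), c(10, 3)), taxa = paste0("t", 1:13))
  expect_equal(max_steps(m13, 1L), 3L)  # minority count
})

test_that("fitch_steps never exceeds max_steps (exhaustive, 5 taxa)", {
  m1 <- load_fixture("table1")
  msub <- morphparsimony:::subset_taxa(m1, m1$taxa[c(2, 7, 11, 16, 24)])
  topos <- enumerate_topologies(msub$taxa)
  for (tr in topos) {
    counts <- morphparsimony:::tree_counts(msub, tr)
    for (ch in seq_len(33)) {
      expect_lte(counts[ch], max_steps(msub, ch))
      expect_gte(counts[ch], min_steps(msub, ch))
    }
  }
})

test_that("m <= s <= g on random simulated column/tree pairs", {
  cases <- 0L
  for (s in 1:25) {
    n <- sample(5:10, 1L)
    tt <- random_tree(n, seed = 700 + s)
    sim <- simulate_matrix(tt, simulation_config(
      n_taxa = n, n_chars = 20, states_per_char = sample(2:4, 1L),
      rate = stats::runif(1, 0.1, 1.5), missing_fraction = 0.1,
      inapplicable_fraction = 0.05), seed = 800 + s)
    m <- sim$matrix
    scorer_tree <- random_tree(m$taxa, seed = 900 + s)
    counts <- morphparsimony:::tree_counts(m, scorer_tree)
    for (ch in seq_len(20)) {
      expect_gte(counts[ch], min_steps(m, ch))
      expect_lte(counts[ch], max_steps(m, ch))
      cases <- cases + 1L
    }
  }
  expect_gte(cases, 500L)
})

test_that("replacing a determinate cell by missing never adds steps", {
  set.seed(42)
  for (s in 1:10) {
    tt <- random_tree(7, seed = 1000 + s)
    sim <- simulate_matrix(tt, simulation_config(n_taxa = 7, n_chars = 10,
                                                 rate = 0.8), seed = 1100 + s)
    m <- sim$matrix
    base <- morphparsimony:::tree_counts(m, tt)
    i <- sample(7, 1L); j <- sample(10, 1L)
    m2 <- m
    m2$cells[i, j] <- "?"
    expect_lte(morphparsimony:::tree_counts(m2, tt)[j], base[j])
  }
})

test_that("parsimony-informativeness distinguishes the two rules", {
  maut <- cm(c("1", "0", "0", "0", "0"), taxa = paste0("t", 1:5))
  expect_false(is_parsimony_informative(maut, 1L))            # autapomorphy
  expect_true(is_parsimony_informative(maut, 1L, "variable"))
  mcst <- cm(c("0", "0", "0", "0"))
  expect_false(is_parsimony_informative(mcst, 1L))
  expect_false(is_parsimony_informative(mcst, 1L, "variable"))
  m1 <- load_fixture("table1")
  strict <- sum(vapply(1:33, function(j) is_parsimony_informative(m1, j),
                       logical(1L)))
  broad <- sum(vapply(1:33, function(j)
    is_parsimony_informative(m1, j, "variable"), logical(1L)))
  expect_equal(strict, 22L)  # golden: 11 columns are autapomorphic/rare-state
  expect_equal(broad, 33L)
})

test_that("diagnostics aggregate cleanly on a homoplasy-free matrix", {
  tt <- parse_newick("((A,B),(C,D),(E,F));")
  m <- split_indicator_matrix(tt, per_split = 1L)
  d <- diagnostics(m, tt, k = 3)
  expect_equal(d$tree_length, ncol(m$cells))  # one step per binary split char
  expect_equal(d$ci, 1)
  expect_equal(d$ri, 1)
  expect_equal(d$fit, ncol(m$cells))
  expect_equal(iw_fit(m, tt, 3), ncol(m$cells))
})

test_that("reported CI/RI use truncation, not rounding", {
  expect_equal(report_decimal(0.536), 0.53)
  expect_equal(report_decimal(0.536, mode = "round"), 0.54)
  expect_equal(report_decimal(0.7575), 0.75)
  expect_equal(report_decimal(0.53), 0.53)
})

test_that("implied weighting: half fit at e = k, and large-k order is -TL", {
  # single character with extra steps e = k gives f = 1/2
  m <- cm(c("0", "1", "0", "1"))          # e = 1 on the AB|CD quartet
  expect_equal(iw_fit(m, quartet("AB|CD"), k = 1), 0.5)
  # ranking by fit at very large k converges to ranking by -TL
  tt <- random_tree(7, seed = 12)
  sim <- simulate_matrix(tt, simulation_config(n_taxa = 7, n_chars = 25,
                                               rate = 0.7), seed = 13)
  m7 <- sim$matrix
  topos <- enumerate_topologies(m7$taxa)
  tls <- vapply(topos, function(t) tree_length(m7, t), numeric(1L))
  fits <- vapply(topos, function(t) iw_fit(m7, t, k = 1e6), numeric(1L))
  # fit-sorted trees have non-decreasing length, and the fit-maximal set is
  # exactly the minimum-length set
  expect_true(!is.unsorted(tls[order(-fits)]))
  expect_setequal(which(fits >= max(fits) - 1e-9), which(tls == min(tls)))
})

test_that("fit is strictly decreasing in any character's extra steps", {
  k <- 3
  f <- function(e) k / (k + e)
  for (e in 0:5) expect_gt(f(e), f(e + 1L))
})

test_that("Sankoff path and Fitch path agree; polytomies score correctly", {
  m1 <- load_fixture("table1")
  tr <- random_addition_tree(m1, seed = 5)
  fit <- tree_length(m1, tr)
  expect_equal(sum(morphparsimony:::sankoff_counts(
    tr, morphparsimony:::masks_for_tree(m1, tr))), fit)
  # every binary representative rescoring to the optimum exactly; the
  # collapsed display trees are their collapses (a soft polytomy stands for
  # a set of resolutions, of which the representative attains the optimum;
  # its hard-polytomy length may exceed it when individually-zero branches
  # cannot all be zero at once)
  res <- heuristic_search(m1, search_config(replicates = 20, seed = 6))
  expect_true(all(vapply(res$binary_trees, function(t)
    tree_length(m1, t), numeric(1L)) == res$best_score))
  for (i in seq_along(res$optimal_trees)) {
    expect_true(all(bipartitions(res$optimal_trees[[i]]) %in%
                      bipartitions(res$binary_trees[[i]])))
    expect_gte(tree_length(m1, res$optimal_trees[[i]]), res$best_score)
  }
})

test_that("collapse rule matches the brute-force minimum edge length", {
  for (s in 1:6) {
    n <- 6
    tt <- random_tree(n, seed = 1200 + s)
    sim <- simulate_matrix(tt, simulation_config(n_taxa = n, n_chars = 8,
                                                 states_per_char = 3,
                                                 rate = 0.9), seed = 1300 + s)
    m <- sim$matrix
    tr <- random_tree(m$taxa, seed = 1400 + s)
    masks <- morphparsimony:::masks_for_tree(m, tr)
    # R two-pass DP
    res <- morphparsimony:::min_branch_lengths(tr, masks)
    # C++ boolean mask, aligned to the same reordered tree
    cpp <- collapse_mask_cpp(res$tree$edge, n, masks)
    internal <- res$tree$edge[, 2L] > n
    expect_equal(unname(cpp[internal]), res$minlen[internal] == 0)
    # brute-force oracle per character per internal edge
    for (r in which(internal)) {
      forced <- sum(vapply(seq_len(ncol(masks)), function(ch)
        brute_force_edge_min(res$tree, masks[, ch], r), integer(1L)))
      expect_equal(res$minlen[r], forced)
    }
  }
})
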