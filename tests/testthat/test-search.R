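# Heuristic and exact tree search

test_that("random addition is deterministic and bounded by the optimum", {
  m1 <- load_fixture("table1")
  a <- random_addition_tree(m1, seed = 42)
  b <- random_addition_tree(m1, seed = 42)
  expect_equal(robinson_foulds(a, b), 0L)

  # 5-taxon submatrix: RAS length >= exact optimum, equality happens
  msub <- morphparsimony:::subset_taxa(m1, m1$taxa[c(1, 6, 12, 18, 25)])
  bb <- branch_and_bound(msub)
  hits <- 0L
  for (s in 1:50) {
    len <- tree_length(msub, random_addition_tree(msub, seed = s))
    expect_gte(len, bb$best_score)
    if (len == bb$best_score) hits <- hits + 1L
  }
  expect_gt(hits, 0L)
})

test_that("neighbourhood sizes and inclusions are correct", {
  for (s in 1:3) {
    tr <- random_tree(6, seed = 40 + s)
    nn <- swap_neighbors(tr, "NNI")
    sp <- swap_neighbors(tr, "SPR")
    tb <- swap_neighbors(tr, "TBR")
    expect_equal(length(nn), 2L * (6L - 3L))
    h0 <- morphparsimony:::tree_hash(tr)
    for (set in list(nn, sp, tb))
      expect_false(h0 %in% hash_set(set))  # no neighbour equals the input
    expect_true(all(hash_set(nn) %in% hash_set(sp)))
    expect_true(all(hash_set(sp) %in% hash_set(tb)))
  }
  # n = 4: NNI neighbourhood is the other two topologies
  q <- quartet("AB|CD")
  expect_setequal(hash_set(swap_neighbors(q, "NNI")),
                  hash_set(list(quartet("AC|BD"), quartet("AD|BC"))))
})

test_that("compiled TBR sweep agrees with the R neighbourhood generator", {
  for (s in 1:4) {
    n <- 6
    tt <- random_tree(n, seed = 50 + s)
    sim <- simulate_matrix(tt, simulation_config(n_taxa = n, n_chars = 12,
                                                 rate = 0.8), seed = 60 + s)
    m <- sim$matrix
    cfg <- search_config()
    ctx <- morphparsimony:::objective_ctx(m, cfg)
    start <- random_tree(m$taxa, seed = 70 + s)
    # R route: score every TBR neighbour
    nbs <- swap_neighbors(start, "TBR")
    r_scores <- vapply(nbs, function(t) tree_length(m, t), numeric(1L))
    # compiled route
    sw <- morphparsimony:::sweep_once(start$edge, ctx, cfg,
                                      cutoff = -Inf, collect = FALSE,
                                      maxcollect = 0L)
    expect_equal(sw$best, min(r_scores))
  }
})

test_that("heuristic search equals exhaustive enumeration on 7 taxa", {
  taxa <- paste0("t", 1:7)
  topos <- enumerate_topologies(taxa)
  for (s in 1:5) {
    tt <- random_tree(taxa, seed = 80 + s)
    sim <- simulate_matrix(tt, simulation_config(n_taxa = 7, n_chars = 15,
                                                 states_per_char = 3,
                                                 rate = 0.6), seed = 90 + s)
    m <- sim$matrix
    exact <- min(vapply(topos, function(t) tree_length(m, t), numeric(1L)))
    res <- heuristic_search(m, search_config(replicates = 5, seed = 100 + s))
    expect_equal(res$best_score, exact)
  }
})

test_that("branch and bound is exact and bounds the heuristics", {
  # a column forcing one quartet topology
  m <- cm(c("00", "00", "11", "11"))
  bb <- branch_and_bound(m, collapse = "none")
  expect_equal(bb$best_score, 2)
  expect_equal(length(bb$optimal_trees), 1L)
  expect_equal(robinson_foulds(bb$optimal_trees[[1L]], quartet("AB|CD")), 0L)

  taxa <- paste0("t", 1:7)
  topos <- enumerate_topologies(taxa)
  for (s in 1:3) {
    tt <- random_tree(taxa, seed = 110 + s)
    sim <- simulate_matrix(tt, simulation_config(n_taxa = 7, n_chars = 12,
                                                 rate = 0.7), seed = 120 + s)
    m7 <- sim$matrix
    lens <- vapply(topos, function(t) tree_length(m7, t), numeric(1L))
    bb7 <- branch_and_bound(m7, collapse = "none")
    expect_equal(bb7$best_score, min(lens))
    # all optimal binary topologies recovered
    opt_hashes <- hash_set(topos[lens == min(lens)])
    expect_setequal(hash_set(bb7$optimal_trees), opt_hashes)
  }
  expect_error(branch_and_bound(load_fixture("table1")), class = "size_error")
})

test_that("heuristic scores never beat branch and bound", {
  m1 <- load_fixture("table1")
  msub <- morphparsimony:::subset_taxa(m1, m1$taxa[seq(1, 26, by = 3)])
  bb <- branch_and_bound(msub)
  for (s in 1:10) {
    res <- heuristic_search(msub, search_config(replicates = 2, seed = s))
    expect_gte(res$best_score, bb$best_score)
  }
})

test_that("search is deterministic given matrix, config and seed", {
  m5 <- load_fixture("table5")
  cfg <- search_config(replicates = 10)
  a <- heuristic_search(m5, cfg, seed = 99)
  b <- heuristic_search(m5, cfg, seed = 99)
  expect_equal(a$best_score, b$best_score)
  expect_identical(hash_set(a$optimal_trees), hash_set(b$optimal_trees))
  expect_identical(a$replicate_log, b$replicate_log)
})

test_that("ratchet never returns a worse score than the plain search", {
  m5 <- load_fixture("table5")
  for (s in 1:3) {
    plain <- heuristic_search(m5, search_config(replicates = 5), seed = s)
    rat <- ratchet_search(m5, search_config(
      replicates = 5,
      ratchet = list(iterations = 5L, perturb_fraction = 0.25,
                     weight_multiplier = 2)), seed = s)
    expect_lte(rat$best_score, plain$best_score)
  }
})

test_that("zero perturbation reduces the ratchet to plain continuation", {
  m5 <- load_fixture("table5")
  plain <- heuristic_search(m5, search_config(replicates = 5), seed = 7)
  rat <- ratchet_search(m5, search_config(
    replicates = 5,
    ratchet = list(iterations = 3L, perturb_fraction = 0, weight_multiplier = 2)),
    seed = 7)
  expect_equal(rat$best_score, plain$best_score)
})

test_that("ratchet escapes NNI local optima at least as often as plain NNI", {
  # two-island construction: characters supporting two conflicting resolved
  # trees; under the weak NNI neighbourhood single-island searches can
  # stall on the minority island
  taxa <- paste0("t", 1:8)
  treeA <- parse_newick("(((t1,t2),(t3,t4)),((t5,t6),(t7,t8)));")
  treeB <- parse_newick("(((t1,t5),(t3,t7)),((t2,t6),(t4,t8)));")
  mA <- split_indicator_matrix(treeA, per_split = 4L)
  mB <- split_indicator_matrix(treeB, per_split = 2L)
  stopifnot(identical(mA$taxa, mB$taxa))
  m <- character_matrix(cbind(mA$cells, mB$cells), taxa = mA$taxa)
  exact <- branch_and_bound(m, collapse = "none")$best_score
  cfgp <- search_config(replicates = 1, swap = "NNI")
  cfgr <- search_config(replicates = 1, swap = "NNI",
                        ratchet = list(iterations = 8L, perturb_fraction = 0.3,
                                       weight_multiplier = 4))
  esc_plain <- esc_rat <- 0L
  for (s in 1:12) {
    if (heuristic_search(m, cfgp, seed = s)$best_score == exact)
      esc_plain <- esc_plain + 1L
    if (ratchet_search(m, cfgr, seed = s)$best_score == exact)
      esc_rat <- esc_rat + 1L
  }
  expect_gte(esc_rat, esc_plain)
})

test_that("implied weighting at huge k recovers the equal-weights optima", {
  taxa <- paste0("t", 1:7)
  topos <- enumerate_topologies(taxa)
  for (s in 1:3) {
    tt <- random_tree(taxa, seed = 130 + s)
    sim <- simulate_matrix(tt, simulation_config(n_taxa = 7, n_chars = 18,
                                                 rate = 0.8), seed = 140 + s)
    m <- sim$matrix
    lens <- vapply(topos, function(t) tree_length(m, t), numeric(1L))
    fits <- vapply(topos, function(t) iw_fit(m, t, k = 1e6), numeric(1L))
    expect_setequal(which(fits >= max(fits) - 1e-10), which(lens == min(lens)))
    res <- iw_search(m, k = 1e6, search_config(replicates = 5), seed = 150 + s)
    expect_equal(ncol(m$cells) - res$best_score, max(fits), tolerance = 1e-9)
  }
})

test_that("search results expose config echo, log and seed", {
  m5 <- load_fixture("table5")
  res <- heuristic_search(m5, search_config(replicates = 4), seed = 5)
  expect_s3_class(res, "mp_search")
  expect_equal(nrow(res$replicate_log), 4L)
  expect_equal(res$seed, 5)
  expect_equal(res$config$swap, "TBR")
  expect_output(print(res), "parsimony search")
})
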