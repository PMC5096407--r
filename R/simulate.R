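# Synthetic character matrices: unordered multistate characters evolved on
# a known tree under a symmetric (Mk) model, with optional random masking
# to missing / inapplicable. This is the generative counterpart of scoring
# multistate characters as non-additive, and the substrate for recovery and
# calibration tests.

#' Simulation configuration
#'
#' @param n_taxa number of taxa (>= 4).
#' @param n_chars number of characters.
#' @param states_per_char states per character: a scalar, or a vector of
#'   length `n_chars` (values 2-4 mirror the range in empirical
#'   morphological matrices; the default 2 reflects the predominance of
#'   binary characters).
#' @param rate expected substitutions per branch (all branches have unit
#'   length); controls the amount of homoplasy.
#' @param missing_fraction probability a cell is masked to `?`.
#' @param inapplicable_fraction probability a cell is masked to `-`.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 26L, n_chars = 33L,
                              states_per_char = 2L, rate = 0.3,
                              missing_fraction = 0, inapplicable_fraction = 0,
                              seed = NULL) {
  stopifnot(n_taxa >= 4L, n_chars >= 1L, rate >= 0,
            missing_fraction >= 0, inapplicable_fraction >= 0,
            missing_fraction + inapplicable_fraction < 1,
            all(states_per_char >= 2L), all(states_per_char <= 10L))
  structure(list(n_taxa = as.integer(n_taxa), n_chars = as.integer(n_chars),
                 states_per_char = as.integer(states_per_char), rate = rate,
                 missing_fraction = missing_fraction,
                 inapplicable_fraction = inapplicable_fraction, seed = seed),
            class = "simulation_config")
}

#' Random unrooted binary tree
#'
#' Uniformly sampled topology by sequential random attachment: each new
#' leaf joins a uniformly chosen branch, which makes every unrooted binary
#' topology equally likely.
#'
#' @param n_taxa number of taxa (>= 4) or a character vector of labels.
#' @param seed integer seed.
#' @return a `phylo`.
#' @export
random_tree <- function(n_taxa, seed = NULL) {
  labels <- if (is.character(n_taxa)) n_taxa else paste0("t", seq_len(n_taxa))
  n <- length(labels)
  if (n < 4L) mp_stop("size_error", "random_tree requires >= 4 taxa")
  with_seed(seed, {
    edges <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
    for (k in 4L:n) {
      r <- sample.int(nrow(edges), 1L)
      newint <- n + k - 2L
      edges <- rbind(edges[-r, , drop = FALSE],
                     c(edges[r, 1L], newint),
                     c(newint, edges[r, 2L]),
                     c(newint, k))
    }
    adj <- vector("list", 2L * n - 2L)
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    phylo_from_adj(adj, labels)
  })
}

# symmetric-model change probability for one unit-length branch at rate r:
# P(end state != start) = (s-1)/s * (1 - exp(-s*r/(s-1)))
mk_change_prob <- function(rate, s) {
  (s - 1) / s * (1 - exp(-s * rate / (s - 1)))
}

#' Simulate a character matrix on a tree
#'
#' Each character evolves independently down the tree under a symmetric
#' transition model (uniform root state, equal exchange rates, unit branch
#' lengths); cells are then masked to missing / inapplicable at the
#' configured rates. Masking is random, not hierarchically linked to a
#' controlling character, because the scorer treats `-` as uncertainty.
#'
#' @param tree a binary `phylo` (its leaves name the taxa).
#' @param config a [simulation_config()].
#' @param seed integer seed (overrides `config$seed`).
#' @return list with `matrix` (a [character_matrix]), and `provenance`
#'   (true tree newick, true unmasked states, mask positions, config,
#'   seed).
#' @export
simulate_matrix <- function(tree, config = simulation_config(),
                            seed = config$seed) {
  tree <- as_unrooted_binary(tree)
  n <- length(tree$tip.label)
  nc <- config$n_chars
  spc <- config$states_per_char
  if (length(spc) == 1L) spc <- rep(spc, nc)
  stopifnot(length(spc) == nc)
  with_seed(seed, {
    tr <- stats::reorder(tree, "postorder")
    M <- n + tr$Nnode
    root <- setdiff(tr$edge[, 1L], tr$edge[, 2L])[1L]
    preorder_edges <- rev(seq_len(nrow(tr$edge)))
    states <- matrix(NA_integer_, M, nc)
    for (ch in seq_len(nc)) {
      s <- spc[ch]
      p_change <- mk_change_prob(config$rate, s)
      states[root, ch] <- sample.int(s, 1L) - 1L
      for (r in preorder_edges) {
        p <- tr$edge[r, 1L]; c <- tr$edge[r, 2L]
        x <- states[p, ch]
        if (stats::runif(1L) < p_change) {
          x <- (x + sample.int(s - 1L, 1L)) %% s
        }
        states[c, ch] <- x
      }
    }
    true_states <- states[seq_len(n), , drop = FALSE]
    cells <- matrix(as.character(true_states), n, nc)
    u <- matrix(stats::runif(n * nc), n, nc)
    mask_missing <- u < config$missing_fraction
    mask_inapp <- !mask_missing &
      u < config$missing_fraction + config$inapplicable_fraction
    cells[mask_missing] <- "?"
    cells[mask_inapp] <- "-"
    m <- character_matrix(cells, taxa = tr$tip.label)
    list(matrix = m,
         provenance = list(true_tree = write_newick(tree),
                           true_states = true_states,
                           mask_missing = which(mask_missing),
                           mask_inapplicable = which(mask_inapp),
                           config = unclass(config),
                           seed = seed))
  })
}
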