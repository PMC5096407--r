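# Independent oracles used across the suite. These deliberately avoid the
# package's scoring path: parsimony lengths are recomputed by brute-force
# minimisation over all internal-node state assignments.

# all state assignments to internal nodes; returns the minimum total number
# of changes over the tree's edges, with ambiguous leaves (bitmask with > 1
# bit) free to take any of their states
brute_force_steps <- function(tree, masks_col) {
  n <- length(tree$tip.label)
  tre <- stats::reorder(tree, "postorder")
  M <- n + tre$Nnode
  states <- which(bitwAnd(bitwShiftL(1L, 0:30), Reduce(bitwOr, masks_col)) > 0L) - 1L
  ns <- length(states)
  if (ns <= 1L) return(0L)
  internal <- (n + 1L):M
  grid <- as.matrix(expand.grid(rep(list(states), length(internal))))
  # leaf options
  leaf_opts <- lapply(seq_len(n), function(i)
    states[bitwAnd(masks_col[i], bitwShiftL(1L, states)) > 0L])
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign_int <- grid[g, ]
    cost <- 0L
    for (r in seq_len(nrow(tre$edge))) {
      p <- tre$edge[r, 1L]; c <- tre$edge[r, 2L]
      sp <- assign_int[p - n]
      if (c <= n) {
        cost <- cost + as.integer(!(sp %in% leaf_opts[[c]]))
      } else {
        cost <- cost + as.integer(assign_int[c - n] != sp)
      }
      if (cost >= best) break
    }
    best <- min(best, cost)
  }
  best
}

# brute-force minimum changes forced on a given edge across all optimal
# assignments (for the collapse-rule oracle); determinate leaves only
brute_force_edge_min <- function(tree, masks_col, edge_row) {
  n <- length(tree$tip.label)
  tre <- stats::reorder(tree, "postorder")
  M <- n + tre$Nnode
  states <- which(bitwAnd(bitwShiftL(1L, 0:30), Reduce(bitwOr, masks_col)) > 0L) - 1L
  ns <- length(states)
  if (ns <= 1L) return(0L)
  internal <- (n + 1L):M
  grid <- as.matrix(expand.grid(rep(list(states), length(internal))))
  leaf_opts <- lapply(seq_len(n), function(i)
    states[bitwAnd(masks_col[i], bitwShiftL(1L, states)) > 0L])
  edge_cost_of <- function(assign_int, r) {
    p <- tre$edge[r, 1L]; c <- tre$edge[r, 2L]
    sp <- assign_int[p - n]
    if (c <= n) as.integer(!(sp %in% leaf_opts[[c]]))
    else as.integer(assign_int[c - n] != sp)
  }
  total <- function(assign_int)
    sum(vapply(seq_len(nrow(tre$edge)), edge_cost_of, integer(1L),
               assign_int = assign_int))
  totals <- apply(grid, 1L, total)
  L <- min(totals)
  opt <- which(totals == L)
  min(vapply(opt, function(g) edge_cost_of(grid[g, ], edge_row), integer(1L)))
}

# quick builders ------------------------------------------------------------

# matrix from a character vector of row strings like "0011?" or "0[01]1"
cm <- function(rows, taxa = LETTERS[seq_along(rows)], outgroup = NULL) {
  cells <- do.call(rbind, lapply(seq_along(rows), function(i)
    morphparsimony:::split_state_string(rows[i], taxa[i])))
  character_matrix(cells, taxa = taxa, outgroup = outgroup)
}

quartet <- function(split = c("AB|CD", "AC|BD", "AD|BC")) {
  split <- match.arg(split)
  txt <- switch(split,
                "AB|CD" = "((A,B),(C,D));",
                "AC|BD" = "((A,C),(B,D));",
                "AD|BC" = "((A,D),(B,C));")
  parse_newick(txt)
}

# matrix whose characters are the split indicators of a tree, `per_split`
# copies each: homoplasy-free by construction
split_indicator_matrix <- function(tree, per_split = 10L) {
  taxa <- sort(tree$tip.label)
  keys <- bipartitions(tree)
  cols <- list()
  for (k in keys) {
    side <- strsplit(k, "|", fixed = TRUE)[[1L]]
    col <- ifelse(taxa %in% side, "1", "0")
    for (i in seq_len(per_split)) cols[[length(cols) + 1L]] <- col
  }
  character_matrix(do.call(cbind, cols), taxa = taxa)
}

tip_masks <- function(m) state_masks(m)

hash_set <- function(trees) sort(vapply(trees, morphparsimony:::tree_hash,
                                        character(1L)))
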