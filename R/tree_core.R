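# Tree model: unrooted (multi)phylogenies over taxon labels, held as ape
# "phylo" objects. Search and scoring operate on unrooted binary trees;
# rooting on the outgroup happens only for display.

#' Parse a newick string
#'
#' @param text a newick string (terminal semicolon required).
#' @return a `phylo` object; polytomies are preserved.
#' @export
parse_newick <- function(text) {
  text <- paste(trimws(text), collapse = "")
  opens <- cumsum((strsplit(text, "")[[1L]] == "(") -
                    (strsplit(text, "")[[1L]] == ")"))
  if (length(opens) && any(opens < 0)) {
    mp_stop("newick_parse_error",
            paste0("unbalanced ')' at offset ", which(opens < 0)[1L]),
            offset = which(opens < 0)[1L])
  }
  if (length(opens) && opens[length(opens)] != 0)
    mp_stop("newick_parse_error",
            paste0("unbalanced '(' (", opens[length(opens)],
                   " unclosed) at offset ", nchar(text)),
            offset = nchar(text))
  if (!grepl(";\\s*$", text))
    mp_stop("newick_parse_error",
            paste0("missing terminal ';' at offset ", nchar(text)),
            offset = nchar(text))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    mp_stop("newick_parse_error", "malformed newick string", offset = NA_integer_)
  tr
}

#' Write a tree as newick
#' @param tree a `phylo` object.
#' @return a newick string.
#' @export
write_newick <- function(tree) ape::write.tree(tree)

# ---------------------------------------------------------------------------
# Splits (bipartitions)
# ---------------------------------------------------------------------------

# Non-trivial bipartitions of an unrooted tree as canonical keys: each split
# is represented by the sorted taxon set on the side NOT containing the
# lexicographically smallest taxon, joined with "|".
split_key <- function(taxa_side, all_taxa) {
  ref <- min(all_taxa)
  side <- if (ref %in% taxa_side) setdiff(all_taxa, taxa_side) else taxa_side
  paste(sort(side), collapse = "|")
}

#' Bipartitions of a tree
#'
#' One canonical key per internal branch; trivial (pendant) splits are
#' excluded, so a star tree yields an empty set.
#'
#' @param tree a `phylo` object with at least 4 leaves.
#' @return character vector of canonical split keys.
#' @export
bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4L) mp_stop("leaf_set_error", "bipartitions need at least 4 leaves")
  labels <- tree$tip.label
  tree <- stats::reorder(tree, "postorder")
  M <- n + tree$Nnode
  below <- vector("list", M)
  for (i in seq_len(n)) below[[i]] <- labels[i]
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1L]
    c <- tree$edge[r, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  keys <- character(0)
  for (r in seq_len(nrow(tree$edge))) {
    c <- tree$edge[r, 2L]
    if (c <= n) next
    side <- below[[c]]
    if (min(length(side), n - length(side)) < 2L) next
    keys <- c(keys, split_key(side, labels))
  }
  unique(keys)
}

check_same_leaves <- function(trees) {
  sets <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(sets)[-1L])
    if (!identical(sets[[i]], sets[[1L]]))
      mp_stop("leaf_set_error", "trees do not share an identical leaf set")
  sets[[1L]]
}

#' Strict consensus of a set of trees
#'
#' The consensus contains exactly the bipartitions present in every input
#' tree; where trees disagree the consensus shows a polytomy.
#'
#' @param trees a list of `phylo` objects (or a `multiPhylo`) on one leaf set
#'   of at least 4 taxa.
#' @return a `phylo` object (possibly multifurcating).
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  taxa <- check_same_leaves(trees)
  if (length(taxa) < 4L)
    mp_stop("leaf_set_error", "consensus needs at least 4 taxa")
  keys <- Reduce(intersect, lapply(trees, bipartitions))
  tree_from_splits(keys, taxa)
}

# Build a (multifurcating) phylo from a compatible split set.
tree_from_splits <- function(keys, taxa) {
  sets <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1L]])
  # orient every set away from the reference taxon already; sets are nested
  n <- length(taxa)
  edges <- matrix(0L, 0L, 2L)
  next_internal <- n + 1L
  rec <- function(tips, subsets) {
    id <- next_internal
    next_internal <<- next_internal + 1L
    # maximal subsets within this group
    keep <- subsets[vapply(subsets, function(s) all(s %in% tips), logical(1L))]
    maximal <- keep[vapply(seq_along(keep), function(i)
      !any(vapply(seq_along(keep), function(j)
        i != j && all(keep[[i]] %in% keep[[j]]) &&
          length(keep[[j]]) > length(keep[[i]]), logical(1L))),
      logical(1L))]
    covered <- character(0)
    for (s in maximal) {
      child <- rec(s, keep[vapply(keep, function(x)
        all(x %in% s) && length(x) < length(s), logical(1L))])
      edges <<- rbind(edges, c(id, child))
      covered <- c(covered, s)
    }
    for (t in setdiff(tips, covered))
      edges <<- rbind(edges, c(id, match(t, taxa)))
    id
  }
  rec(taxa, sets)
  tr <- structure(list(edge = edges, tip.label = taxa,
                       Nnode = next_internal - n - 1L),
                  class = "phylo")
  tr
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of the bipartition sets of two trees on the
#' same leaf set; 0 iff the topologies are identical.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  check_same_leaves(list(t1, t2))
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# topology identity hash (collapsed or binary trees alike)
tree_hash <- function(tree) {
  paste(sort(bipartitions(tree)), collapse = ";")
}

# ---------------------------------------------------------------------------
# Adjacency helpers for R-side tree surgery (neighbourhood generation,
# enumeration). Nodes: tips 1..n, internals n+1..2n-2.
# ---------------------------------------------------------------------------

adj_from_phylo <- function(tree) {
  n <- length(tree$tip.label)
  M <- 2L * n - 2L
  adj <- vector("list", M)
  for (r in seq_len(nrow(tree$edge))) {
    a <- tree$edge[r, 1L]
    b <- tree$edge[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# canonicalize an adjacency into an ape phylo (root at tip 1's neighbour,
# internals renumbered in preorder)
phylo_from_adj <- function(adj, tip_labels) {
  n <- length(tip_labels)
  M <- 2L * n - 2L
  newid <- integer(M)
  newid[seq_len(n)] <- seq_len(n)
  root <- adj[[1L]][1L]
  nextid <- n + 1L
  edges <- matrix(0L, 2L * n - 3L, 2L)
  row <- 0L
  stack <- list(c(root, 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    x <- top[1L]; p <- top[2L]
    if (x > n) {
      newid[x] <- nextid
      nextid <- nextid + 1L
    }
    if (p != 0L) {
      row <- row + 1L
      edges[row, ] <- c(newid[p], newid[x])
    }
    for (y in rev(adj[[x]])) if (y != p) stack[[length(stack) + 1L]] <- c(y, x)
  }
  structure(list(edge = edges, tip.label = tip_labels, Nnode = n - 2L),
            class = "phylo")
}

# ensure an unrooted, binary phylo on >= 4 tips (unroots a rooted input)
as_unrooted_binary <- function(tree) {
  if (!ape::is.binary(tree)) {
    tree <- tryCatch(ape::multi2di(tree, random = FALSE), error = function(e) tree)
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (!ape::is.binary(tree))
    mp_stop("tree_shape_error", "a fully resolved (binary) tree is required")
  tree
}

edge_pairs_from_adj <- function(adj) {
  out <- list()
  for (x in seq_along(adj))
    for (y in adj[[x]]) if (y > x) out[[length(out) + 1L]] <- c(x, y)
  out
}

# ---------------------------------------------------------------------------
# Topology enumeration (exact oracle substrate)
# ---------------------------------------------------------------------------

#' Enumerate all unrooted binary topologies
#'
#' Yields every distinct unrooted binary tree on the given taxa exactly once
#' by recursive stepwise addition; the count is (2n-5)!!.
#'
#' @param taxa character vector of 4 to `max_n` taxon names.
#' @param max_n guard bound (default 9; 10395 trees at n = 8).
#' @return list of `phylo` objects.
#' @export
enumerate_topologies <- function(taxa, max_n = 9L) {
  n <- length(taxa)
  if (n < 4L || n > max_n)
    mp_stop("size_error",
            sprintf("enumeration supports 4..%d taxa (got %d)", max_n, n))
  # start: the single unrooted tree on 3 tips (star at internal n+1)
  base <- list(rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)))
  for (k in 4L:n) {
    newint <- n + k - 2L
    nxt <- vector("list", length(base) * (2L * k - 5L))
    ii <- 0L
    for (ed in base) {
      for (r in seq_len(nrow(ed))) {
        e2 <- rbind(ed[-r, , drop = FALSE],
                    c(ed[r, 1L], newint),
                    c(newint, ed[r, 2L]),
                    c(newint, k))
        ii <- ii + 1L
        nxt[[ii]] <- e2
      }
    }
    base <- nxt
  }
  lapply(base, function(ed) {
    adj <- vector("list", 2L * n - 2L)
    for (r in seq_len(nrow(ed))) {
      a <- ed[r, 1L]; b <- ed[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    phylo_from_adj(adj, taxa)
  })
}

#' Smallest rooted clade containing a set of taxa
#'
#' Roots the tree on the outgroup and returns the tip labels of the
#' smallest clade containing every taxon in `taxa`; used e.g. to test
#' whether one genus is nested within another.
#'
#' @param tree a `phylo`.
#' @param outgroup outgroup taxon for rooting.
#' @param taxa taxon labels that the clade must contain.
#' @return character vector of the clade's tip labels.
#' @export
smallest_clade <- function(tree, outgroup, taxa) {
  rooted <- root_on_outgroup(tree, outgroup)
  if (!all(taxa %in% rooted$tip.label))
    mp_stop("leaf_set_error", "clade taxa missing from tree")
  if (length(taxa) == 1L) return(taxa)
  node <- ape::getMRCA(rooted, taxa)
  if (node == length(rooted$tip.label) + 1L) return(rooted$tip.label)
  ape::extract.clade(rooted, node)$tip.label
}

#' Root a tree on the outgroup for display
#'
#' Parsimony scores are root-invariant; rooting is presentation only.
#'
#' @param tree a `phylo` object.
#' @param outgroup outgroup taxon label.
#' @return rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    mp_stop("leaf_set_error", paste0("outgroup '", outgroup, "' not in tree"))
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
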