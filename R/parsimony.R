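# Parsimony scoring and homoplasy diagnostics for unordered (non-additive)
# characters. Binary trees go through the compiled Fitch engine;
# multifurcating trees fall back to a unit-cost Sankoff dynamic programme,
# which gives the identical minimum-change count.

# match tree tips to matrix taxa; returns the tree with tips relabelled to
# row indices checked against m$taxa
check_tree_matrix <- function(m, tree) {
  norm <- internal_name(m$taxa)
  tl <- tree$tip.label
  idx <- match(tl, m$taxa)
  idx[is.na(idx)] <- match(tl[is.na(idx)], norm)
  if (anyNA(idx) || length(idx) != length(m$taxa) || anyDuplicated(idx))
    mp_stop("leaf_set_error",
            "tree leaves do not match the matrix taxa exactly")
  idx
}

# reorder matrix rows so that row i corresponds to tip i of the tree
masks_for_tree <- function(m, tree, variable_as = "missing") {
  idx <- check_tree_matrix(m, tree)
  state_masks(m, variable_as = variable_as)[idx, , drop = FALSE]
}

# per-character minimum-change counts on an arbitrary (possibly
# multifurcating) tree via unit-cost Sankoff
sankoff_counts <- function(tree, masks) {
  n <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  M <- n + tree$Nnode
  nc <- ncol(masks)
  counts <- integer(nc)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  porder <- unique(tree$edge[, 1L])  # postorder parents
  for (ch in seq_len(nc)) {
    states <- which(bitwAnd(bitwShiftL(1L, 0:30), Reduce(bitwOr, masks[, ch])) > 0L) - 1L
    ns <- length(states)
    if (ns == 0L) next
    INF <- 1e9
    D <- matrix(INF, M, ns)
    for (i in seq_len(n)) {
      mask <- masks[i, ch]
      D[i, ] <- ifelse(bitwAnd(mask, bitwShiftL(1L, states)) > 0L, 0, INF)
    }
    for (p in porder) {
      acc <- numeric(ns)
      for (k in kids[[as.character(p)]]) {
        best <- min(D[k, ])
        acc <- acc + pmin(D[k, ], best + 1)
      }
      D[p, ] <- acc
    }
    counts[ch] <- as.integer(min(D[root, ]))
  }
  counts
}

# per-character step counts for any tree spanning the matrix taxa
tree_counts <- function(m, tree, variable_as = "missing") {
  masks <- masks_for_tree(m, tree, variable_as)
  if (ape::is.binary(tree) && !ape::is.rooted(tree)) {
    fitch_counts_cpp(tree$edge, length(tree$tip.label), masks)
  } else if (ape::is.binary(tree)) {
    tr <- ape::unroot(tree)
    masks <- masks_for_tree(m, tr, variable_as)
    fitch_counts_cpp(tr$edge, length(tr$tip.label), masks)
  } else {
    sankoff_counts(tree, masks)
  }
}

#' Fitch steps of one character on a tree
#'
#' Minimum number of state changes required by character `character` on
#' `tree`, treating the character as unordered. Missing, inapplicable and
#' variable cells carry the full observed-state set and never add steps.
#' A column without any determinate cell scores 0 with a warning.
#'
#' @param m a [character_matrix].
#' @param tree a `phylo` spanning the matrix taxa.
#' @param character character index.
#' @return integer step count (root-invariant).
#' @export
fitch_steps <- function(m, tree, character) {
  col <- m$cells[, character]
  if (!any(!(col %in% c("?", "-", "V")))) {
    mp_warn("uninformative_column_warning",
            paste0("character ", character,
                   " has no determinate cells; steps defined as 0"))
    return(0L)
  }
  tree_counts(m, tree)[character]
}

#' Tree length (total parsimony steps)
#'
#' @param m a [character_matrix].
#' @param tree a `phylo` spanning the matrix taxa.
#' @return integer: sum of per-character Fitch steps under equal weights.
#' @export
tree_length <- function(m, tree) {
  sum(tree_counts(m, tree))
}

#' Minimum conceivable steps of a character
#'
#' Number of distinct determinately observed states minus one; the length
#' the character would need on a perfectly clean tree.
#'
#' @param m a [character_matrix].
#' @param character character index.
#' @return non-negative integer.
#' @export
min_steps <- function(m, character) {
  col <- m$cells[, character]
  det <- col[grepl("^[0-9]$", col)]
  max(0L, length(unique(det)) - 1L)
}

#' Maximum steps of a character on any tree
#'
#' The length on the worst (star-equivalent) tree for an unordered
#' character: the total determinate observation count minus the count of
#' the most frequent state.
#'
#' @param m a [character_matrix].
#' @param character character index.
#' @return non-negative integer.
#' @export
max_steps <- function(m, character) {
  col <- m$cells[, character]
  det <- col[grepl("^[0-9]$", col)]
  if (!length(det)) return(0L)
  tab <- table(det)
  as.integer(sum(tab) - max(tab))
}

#' Is a character parsimony-informative?
#'
#' Under the strict (textbook) rule, true iff at least two states are each
#' observed determinately in at least two taxa; only such characters can
#' discriminate among trees, and autapomorphies fail. Under
#' `rule = "variable"`, true iff at least two states are observed at all —
#' the broader accounting that several cladistics programs print and the
#' one under which every character of the packaged 26-taxon matrix counts
#' as informative (its published consistency index is only consistent with
#' that accounting; see the methods vignette).
#'
#' @param m a [character_matrix].
#' @param character character index.
#' @param rule `"strict"` (default) or `"variable"`.
#' @return logical.
#' @export
is_parsimony_informative <- function(m, character,
                                     rule = c("strict", "variable")) {
  rule <- match.arg(rule)
  col <- m$cells[, character]
  det <- col[grepl("^[0-9]$", col)]
  if (rule == "strict") sum(table(det) >= 2L) >= 2L
  else length(unique(det)) >= 2L
}

#' Truncate to a fixed number of decimals
#'
#' Reporting convention for printed CI/RI values: truncation (floor), the
#' apparent convention of the published values; full precision is retained
#' in the diagnostics object.
#'
#' @param x numeric.
#' @param digits decimals kept.
#' @param mode `"truncate"` (default) or `"round"`.
#' @return numeric.
#' @export
report_decimal <- function(x, digits = 2L, mode = c("truncate", "round")) {
  mode <- match.arg(mode)
  if (mode == "round") return(round(x, digits))
  trunc(x * 10^digits + 1e-9) / 10^digits
}

#' Homoplasy diagnostics of a tree
#'
#' Per-character steps `s`, minimum `m`, maximum `g`, extra steps
#' `e = s - m` and implied-weighting fit `f = k/(k+e)`, with ensemble
#' aggregates: tree length `TL = sum(s)`, consistency index
#' `CI = sum(m)/sum(s)` over parsimony-informative characters only,
#' retention index `RI = (sum(g)-sum(s))/(sum(g)-sum(m))` over all
#' characters, and total fit `F = sum(f)`.
#'
#' @param m a [character_matrix].
#' @param tree a `phylo` spanning the matrix taxa.
#' @param k concavity constant of the implied-weighting fit (default 3).
#' @param informative filter behind the CI's "informative characters
#'   only": `"variable"` (default; at least two observed states — the
#'   accounting the published values follow) or `"strict"` (at least two
#'   states each in two taxa). RI always uses all characters.
#' @return object of class `mp_diagnostics`: a list with `per_character`
#'   (data frame), `tree_length`, `ci`, `ri`, `fit`, `k`, and two-decimal
#'   truncated `ci_reported`, `ri_reported`.
#' @export
diagnostics <- function(m, tree, k = 3,
                        informative = c("variable", "strict")) {
  informative <- match.arg(informative)
  if (k <= 0) mp_stop("concavity_error", "concavity k must be > 0")
  nc <- ncol(m$cells)
  s <- as.integer(tree_counts(m, tree))
  mi <- vapply(seq_len(nc), function(j) min_steps(m, j), integer(1L))
  gi <- vapply(seq_len(nc), function(j) max_steps(m, j), integer(1L))
  info <- vapply(seq_len(nc), function(j)
    is_parsimony_informative(m, j, rule = informative), logical(1L))
  e <- pmax(0L, s - mi)
  f <- k / (k + e)
  per <- data.frame(index = seq_len(nc), steps = s, min = mi, max = gi,
                    extra = e, fit = f, informative = info)
  TL <- sum(s)
  ci <- if (sum(s[info]) > 0) sum(mi[info]) / sum(s[info]) else NA_real_
  ri_def <- sum(gi) - sum(mi) > 0
  if (!ri_def)
    mp_warn("ri_undefined_warning",
            "no informative variation: retention index undefined")
  ri <- if (ri_def) (sum(gi) - sum(s)) / (sum(gi) - sum(mi)) else NA_real_
  structure(list(per_character = per,
                 tree_length = TL,
                 ci = ci,
                 ri = ri,
                 fit = sum(f),
                 k = k,
                 ci_reported = if (is.na(ci)) NA_real_ else report_decimal(ci),
                 ri_reported = if (is.na(ri)) NA_real_ else report_decimal(ri)),
            class = "mp_diagnostics")
}

#' @export
print.mp_diagnostics <- function(x, ...) {
  cat(sprintf("TL %d, CI %.4f (reported %.2f), RI %.4f (reported %.2f), F %.4f (k = %g)\n",
              x$tree_length, x$ci, x$ci_reported, x$ri, x$ri_reported,
              x$fit, x$k))
  invisible(x)
}

#' Implied-weighting fit of a tree
#'
#' The Goloboff fit `F = sum_i k/(k + e_i)` with `e_i` the extra
#' (homoplastic) steps of character `i` on `tree`. Larger is better; a
#' homoplasy-free tree attains `F = nchar`.
#'
#' @param m a [character_matrix].
#' @param tree a `phylo` spanning the matrix taxa.
#' @param k concavity constant (> 0).
#' @return numeric fit.
#' @export
iw_fit <- function(m, tree, k = 3) {
  if (k <= 0) mp_stop("concavity_error", "concavity k must be > 0")
  nc <- ncol(m$cells)
  s <- as.integer(tree_counts(m, tree))
  mi <- vapply(seq_len(nc), function(j) min_steps(m, j), integer(1L))
  e <- pmax(0L, s - mi)
  sum(k / (k + e))
}

#' Export diagnostics as a TSV table
#' @param d an `mp_diagnostics` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_diagnostics_tsv <- function(d, path) {
  utils::write.table(d$per_character, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export diagnostics as JSON
#' @param d an `mp_diagnostics` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_diagnostics_json <- function(d, path) {
  jsonlite::write_json(list(tree_length = d$tree_length, ci = d$ci,
                            ri = d$ri, fit = d$fit, k = d$k,
                            ci_reported = d$ci_reported,
                            ri_reported = d$ri_reported,
                            per_character = d$per_character),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Branch collapsing: a branch is collapsed when its minimum possible length
# over all most-parsimonious reconstructions is zero (the common convention
# for counting distinct optimal trees). Computed exactly per character with
# a two-pass unit-cost Sankoff DP.
# ---------------------------------------------------------------------------

# per internal edge: minimum total changes assignable to that edge across
# all minimum-length reconstructions, summed over characters
min_branch_lengths <- function(tree, masks) {
  n <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  M <- n + tree$Nnode
  nc <- ncol(masks)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  porder <- unique(tree$edge[, 1L])
  parent <- integer(M)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_row <- integer(M)
  edge_row[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  minlen <- numeric(nrow(tree$edge))
  INF <- 1e9
  for (ch in seq_len(nc)) {
    allmask <- Reduce(bitwOr, masks[, ch])
    states <- which(bitwAnd(bitwShiftL(1L, 0:30), allmask) > 0L) - 1L
    ns <- length(states)
    if (ns <= 1L) next
    D <- matrix(INF, M, ns)
    for (i in seq_len(n))
      D[i, ] <- ifelse(bitwAnd(masks[i, ch], bitwShiftL(1L, states)) > 0L, 0, INF)
    TRM <- matrix(0, M, ns)  # min(D[k, y], minD[k] + 1), child k folded at parent
    for (p in porder) {
      acc <- numeric(ns)
      for (k in kids[[as.character(p)]]) {
        TRM[k, ] <- pmin(D[k, ], min(D[k, ]) + 1)
        acc <- acc + TRM[k, ]
      }
      D[p, ] <- acc
    }
    L <- min(D[root, ])
    # preorder up-pass. U[x, y]: min cost outside subtree(x) given x = y
    # (including a possible change on the edge above x); OUT[y]: the same
    # but conditioned on parent(x) = y and excluding that edge's change.
    U <- matrix(NA_real_, M, ns)
    U[root, ] <- 0
    for (p in rev(porder)) {
      Qp <- D[p, ] + U[p, ]
      for (k in kids[[as.character(p)]]) {
        OUT <- Qp - TRM[k, ]
        if (k > n && min(OUT + D[k, ]) > L + 1e-9)
          minlen[edge_row[k]] <- minlen[edge_row[k]] + 1
        U[k, ] <- pmin(OUT, min(OUT) + 1)
      }
    }
  }
  list(minlen = minlen, edge = tree$edge, tree = tree)
}

#' Collapse branches of minimum length zero
#'
#' Collapses every internal branch that can carry zero changes in some
#' minimum-length reconstruction of every character (the usual rule behind
#' counts of distinct most-parsimonious trees).
#'
#' @param m a [character_matrix].
#' @param tree a binary `phylo` spanning the matrix taxa.
#' @return a `phylo`, possibly multifurcating.
#' @export
collapse_zero_branches <- function(m, tree) {
  tree <- as_unrooted_binary(tree)
  masks <- masks_for_tree(m, tree)
  collapsible <- collapse_mask_cpp(tree$edge, length(tree$tip.label), masks)
  tree$edge.length <- ifelse(collapsible, 0, 1)
  out <- ape::di2multi(tree, tol = 1e-8)
  out$edge.length <- NULL
  out
}
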