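# Tree search: random addition sequences, branch swapping (NNI/SPR/TBR),
# parsimony ratchet, exact branch and bound, and implied weighting.
#
# The default search follows the classic two-phase heuristic: many
# replicates of random taxon addition followed by branch swapping, keeping
# up to `hold` trees at the best score per replicate, then swapping through
# the pooled optima until closure. TBR neighbourhoods are scored by the
# compiled sweep; NNI and SPR searches use the R neighbourhood generators.

#' Search configuration
#'
#' @param replicates number of random-addition replicates. The default 200
#'   is a desk-scale budget; the published analyses used 10,000, which the
#'   26-taxon matrix does not need to reach the same optimum.
#' @param hold maximum trees held at the best score per replicate (and per
#'   closure queue step).
#' @param swap branch-swapping neighbourhood: `"TBR"`, `"SPR"` or `"NNI"`.
#' @param objective `"equal_weights"` or `"implied_weighting"`.
#' @param k concavity constant when `objective = "implied_weighting"`.
#' @param ratchet optional list with `iterations`, `perturb_fraction`,
#'   `weight_multiplier` enabling the parsimony ratchet.
#' @param seed integer seed; every stochastic choice derives from it.
#' @param collapse rule for counting distinct optima: `"min_length_zero"`
#'   (collapse branches whose minimum length over all optimal
#'   reconstructions is zero) or `"none"`.
#' @param maxtrees cap on the global optimal-tree pool.
#' @return a list of class `search_config`.
#' @export
search_config <- function(replicates = 200L, hold = 100L,
                          swap = c("TBR", "SPR", "NNI"),
                          objective = c("equal_weights", "implied_weighting"),
                          k = 3, ratchet = NULL, seed = NULL,
                          collapse = c("min_length_zero", "none"),
                          maxtrees = 1000L) {
  swap <- match.arg(swap)
  objective <- match.arg(objective)
  collapse <- match.arg(collapse)
  stopifnot(replicates >= 1L, hold >= 1L, maxtrees >= 1L, k > 0)
  if (!is.null(ratchet)) {
    stopifnot(is.list(ratchet),
              ratchet$iterations >= 1L,
              ratchet$perturb_fraction >= 0, ratchet$perturb_fraction < 1,
              ratchet$weight_multiplier >= 1)
  }
  structure(list(replicates = as.integer(replicates), hold = as.integer(hold),
                 swap = swap, objective = objective, k = k, ratchet = ratchet,
                 seed = seed, collapse = collapse,
                 maxtrees = as.integer(maxtrees)),
            class = "search_config")
}

# objective plumbing shared by the search entry points
objective_ctx <- function(m, cfg, weights = NULL) {
  masks <- state_masks(m)
  nc <- ncol(masks)
  if (is.null(weights)) weights <- rep(1, nc)
  iw <- cfg$objective == "implied_weighting"
  minsteps <- vapply(seq_len(nc), function(j) min_steps(m, j), integer(1L))
  list(masks = masks, weights = weights, iw = iw, k = cfg$k,
       minsteps = minsteps)
}

score_edge <- function(edge, ctx) {
  counts <- fitch_counts_cpp(edge, nrow(ctx$masks), ctx$masks)
  if (!ctx$iw) sum(ctx$weights * counts)
  else {
    e <- pmax(0, counts - ctx$minsteps)
    sum(e / (ctx$k + e))
  }
}

#' Random addition tree
#'
#' Greedy stepwise addition in a seeded random taxon order: each taxon is
#' inserted on the branch that minimises tree length (first-encountered
#' branch on ties), giving a deterministic result for a given seed.
#'
#' @param m a [character_matrix] with at least 4 taxa.
#' @param seed integer seed.
#' @return a `phylo`.
#' @export
random_addition_tree <- function(m, seed = NULL) {
  n <- length(m$taxa)
  if (n < 4L) mp_stop("size_error", "stepwise addition requires >= 4 taxa")
  cfg <- search_config()
  ctx <- objective_ctx(m, cfg)
  ord <- with_seed(seed, sample.int(n))
  edge <- ras_tree_cpp(ord, ctx$masks, ctx$weights, FALSE, 3, ctx$minsteps)
  tr <- structure(list(edge = edge, tip.label = m$taxa, Nnode = n - 2L),
                  class = "phylo")
  tr
}

# ---------------------------------------------------------------------------
# R-side neighbourhood generators (reference implementations; also the
# engine for NNI/SPR-configured searches)
# ---------------------------------------------------------------------------

#' Branch-swapping neighbourhood of a tree
#'
#' Distinct neighbour topologies of an unrooted binary tree under the given
#' move. The NNI neighbourhood has 2(n-3) members; SPR is a superset of
#' NNI, and TBR a superset of SPR.
#'
#' @param tree an unrooted binary `phylo` with at least 4 leaves.
#' @param move `"NNI"`, `"SPR"` or `"TBR"`.
#' @return list of `phylo` objects (no neighbour equals the input).
#' @export
swap_neighbors <- function(tree, move = c("NNI", "SPR", "TBR")) {
  move <- match.arg(move)
  tree <- as_unrooted_binary(tree)
  n <- length(tree$tip.label)
  if (n < 4L) mp_stop("size_error", "branch swapping requires >= 4 leaves")
  adj <- adj_from_phylo(tree)
  out <- switch(move,
                NNI = nni_neighbors_adj(adj, n),
                SPR = tbr_neighbors_adj(adj, n, spr_only = TRUE),
                TBR = tbr_neighbors_adj(adj, n, spr_only = FALSE))
  trees <- lapply(out, phylo_from_adj, tip_labels = tree$tip.label)
  # dedupe topologies and drop any representation of the input
  h0 <- tree_hash(tree)
  keep <- list()
  seen <- character(0)
  for (t in trees) {
    h <- tree_hash(t)
    if (h == h0 || h %in% seen) next
    seen <- c(seen, h)
    keep[[length(keep) + 1L]] <- t
  }
  keep
}

nni_neighbors_adj <- function(adj, n) {
  out <- list()
  for (u in seq_along(adj)) {
    if (u <= n) next
    for (v in adj[[u]]) {
      if (v <= n || v < u) next
      a <- setdiff(adj[[u]], v)
      b <- setdiff(adj[[v]], u)
      for (bx in b) {
        a2 <- a[2L]
        adj2 <- adj
        adj2[[u]] <- c(setdiff(adj2[[u]], a2), bx)
        adj2[[v]] <- c(setdiff(adj2[[v]], bx), a2)
        adj2[[a2]] <- c(setdiff(adj2[[a2]], u), v)
        adj2[[bx]] <- c(setdiff(adj2[[bx]], v), u)
        out[[length(out) + 1L]] <- adj2
      }
    }
  }
  out
}

# full TBR enumeration in R: bisect every edge, contract the stumps,
# reattach at every edge pair (SPR restricts one side to its original
# attachment edge or a lone tip)
tbr_neighbors_adj <- function(adj, n, spr_only = FALSE) {
  out <- list()
  edges <- edge_pairs_from_adj(adj)
  for (e in edges) {
    u <- e[1L]; v <- e[2L]
    base <- adj
    base[[u]] <- setdiff(base[[u]], v)
    base[[v]] <- setdiff(base[[v]], u)
    sides <- list()
    for (w in c(u, v)) {
      if (w <= n) {
        sides[[length(sides) + 1L]] <-
          list(single = TRUE, tip = w, contracted = NULL)
      } else {
        pr <- base[[w]]
        b2 <- base
        b2[[w]] <- integer(0)
        b2[[pr[1L]]] <- c(setdiff(b2[[pr[1L]]], w), pr[2L])
        b2[[pr[2L]]] <- c(setdiff(b2[[pr[2L]]], w), pr[1L])
        # edges of this component
        comp <- component_nodes(b2, pr[1L])
        ce <- list()
        for (x in comp) for (y in b2[[x]]) if (y > x && y %in% comp)
          ce[[length(ce) + 1L]] <- c(x, y)
        sides[[length(sides) + 1L]] <-
          list(single = FALSE, node = w, contracted = sort(pr), edges = ce,
               adj = b2)
      }
    }
    s1 <- sides[[1L]]; s2 <- sides[[2L]]
    e1list <- if (s1$single) list(NULL) else s1$edges
    e2list <- if (s2$single) list(NULL) else s2$edges
    for (i1 in seq_along(e1list)) {
      orig1 <- s1$single ||
        identical(sort(e1list[[i1]]), s1$contracted)
      for (i2 in seq_along(e2list)) {
        orig2 <- s2$single ||
          identical(sort(e2list[[i2]]), s2$contracted)
        if (orig1 && orig2) next
        if (spr_only && !orig1 && !orig2) next
        a2 <- reattach_adj(adj, n, u, v, e1list[[i1]], e2list[[i2]])
        out[[length(out) + 1L]] <- a2
      }
    }
  }
  out
}

component_nodes <- function(adj, start) {
  seen <- integer(0)
  stack <- start
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x %in% seen) next
    seen <- c(seen, x)
    stack <- c(stack, setdiff(adj[[x]], seen))
  }
  seen
}

reattach_adj <- function(adj, n, u, v, e1, e2) {
  a <- adj
  a[[u]] <- setdiff(a[[u]], v)
  a[[v]] <- setdiff(a[[v]], u)
  for (w in c(u, v)) {
    if (w > n) {
      pr <- a[[w]]
      a[[w]] <- integer(0)
      a[[pr[1L]]] <- c(setdiff(a[[pr[1L]]], w), pr[2L])
      a[[pr[2L]]] <- c(setdiff(a[[pr[2L]]], w), pr[1L])
    }
  }
  if (!is.null(e1)) {
    a[[e1[1L]]] <- c(setdiff(a[[e1[1L]]], e1[2L]), u)
    a[[e1[2L]]] <- c(setdiff(a[[e1[2L]]], e1[1L]), u)
    a[[u]] <- c(e1[1L], e1[2L])
  }
  if (!is.null(e2)) {
    a[[e2[1L]]] <- c(setdiff(a[[e2[1L]]], e2[2L]), v)
    a[[e2[2L]]] <- c(setdiff(a[[e2[2L]]], e2[1L]), v)
    a[[v]] <- c(e2[1L], e2[2L])
  }
  a[[u]] <- c(a[[u]], v)
  a[[v]] <- c(a[[v]], u)
  a
}

# ---------------------------------------------------------------------------
# Hill climbing
# ---------------------------------------------------------------------------

EPS <- 1e-7

# one sweep of the configured neighbourhood; returns best score and the
# neighbours at or below `cutoff`
sweep_once <- function(edge, ctx, cfg, cutoff, collect, maxcollect) {
  if (cfg$swap == "TBR" || cfg$swap == "SPR") {
    tbr_sweep_cpp(edge, nrow(ctx$masks), ctx$masks, ctx$weights, ctx$iw,
                  ctx$k, ctx$minsteps, cutoff, collect, maxcollect,
                  if (cfg$swap == "SPR") 1L else 0L)
  } else {
    n <- nrow(ctx$masks)
    tr <- structure(list(edge = edge, tip.label = as.character(seq_len(n)),
                         Nnode = n - 2L), class = "phylo")
    nbs <- swap_neighbors(tr, cfg$swap)
    best <- Inf
    trees <- list()
    scores <- numeric(0)
    for (nb in nbs) {
      s <- score_edge(nb$edge, ctx)
      if (s < best) best <- s
      if (collect && s <= cutoff + 1e-9 && length(trees) < maxcollect) {
        trees[[length(trees) + 1L]] <- nb$edge
        scores <- c(scores, s)
      }
    }
    list(best = best, trees = trees, scores = scores)
  }
}

edge_hash <- function(edge, n) tree_hash_cpp(edge, n)

# pool identity: under the min-length-zero rule two binary resolutions of
# the same collapsed optimum count once
pool_hash <- function(edge, ctx, cfg) {
  if (cfg$collapse == "min_length_zero")
    collapsed_hash_cpp(edge, nrow(ctx$masks), ctx$masks)
  else edge_hash(edge, nrow(ctx$masks))
}

# strict descent: follow improving neighbours until a local optimum
descend <- function(edge, ctx, cfg) {
  score <- score_edge(edge, ctx)
  repeat {
    sw <- sweep_once(edge, ctx, cfg, cutoff = score - EPS, collect = TRUE,
                     maxcollect = 50L)
    if (length(sw$trees)) {
      pick <- which.min(sw$scores)
      edge <- sw$trees[[pick]]
      score <- sw$scores[pick]
    } else break
  }
  list(score = score, edge = edge)
}

# one replicate: descend, then gather up to `hold` equal-score neighbours
# from the final sweep (full plateau closure happens on the global pool)
climb <- function(edge, ctx, cfg) {
  d <- descend(edge, ctx, cfg)
  sw <- sweep_once(d$edge, ctx, cfg, cutoff = d$score + EPS, collect = TRUE,
                   maxcollect = cfg$hold)
  keep <- list(d$edge)
  for (i in seq_along(sw$trees))
    if (sw$scores[i] <= d$score + EPS && length(keep) < cfg$hold)
      keep[[length(keep) + 1L]] <- sw$trees[[i]]
  list(score = d$score, edges = keep)
}

# swap every pooled optimum until closure: no neighbour improves the pool
# score or adds a new optimal topology
closure <- function(pool, hashes, best, ctx, cfg) {
  n <- nrow(ctx$masks)
  queue <- pool
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    sw <- sweep_once(cur, ctx, cfg, cutoff = best + EPS, collect = TRUE,
                     maxcollect = cfg$maxtrees)
    if (sw$best < best - EPS) {
      d <- descend(cur, ctx, cfg)
      best <- d$score
      pool <- list(d$edge)
      hashes <- pool_hash(d$edge, ctx, cfg)
      queue <- pool
      next
    }
    for (i in seq_along(sw$trees)) {
      if (sw$scores[i] > best + EPS) next
      h <- pool_hash(sw$trees[[i]], ctx, cfg)
      if (h %in% hashes || length(pool) >= cfg$maxtrees) next
      hashes <- c(hashes, h)
      pool[[length(pool) + 1L]] <- sw$trees[[i]]
      queue[[length(queue) + 1L]] <- sw$trees[[i]]
    }
  }
  list(best = best, pool = pool, hashes = hashes)
}

finalize_result <- function(m, cfg, best, pool_edges, replicate_log, seed,
                            ctx) {
  n <- length(m$taxa)
  trees <- lapply(pool_edges, function(e)
    structure(list(edge = e, tip.label = m$taxa, Nnode = n - 2L),
              class = "phylo"))
  collapsed <- if (cfg$collapse == "min_length_zero")
    lapply(trees, function(t) collapse_zero_branches(m, t))
  else trees
  keep <- !duplicated(vapply(collapsed, tree_hash, character(1L)))
  res <- structure(list(best_score = best,
                        optimal_trees = collapsed[keep],
                        binary_trees = trees[keep],
                        replicate_log = replicate_log,
                        seed = seed,
                        config = cfg,
                        objective = cfg$objective,
                        collapse_rule = cfg$collapse),
                   class = "mp_search")
  if (cfg$objective == "implied_weighting") {
    # report fit on the maximisation scale
    res$best_fit <- ncol(m$cells) - best
  }
  res
}

#' @export
print.mp_search <- function(x, ...) {
  if (x$objective == "implied_weighting") {
    cat(sprintf("implied-weighting search (k = %g): best fit %.4f, %d optimal tree(s)\n",
                x$config$k, x$best_fit, length(x$optimal_trees)))
  } else {
    cat(sprintf("parsimony search: best length %g, %d optimal tree(s)\n",
                x$best_score, length(x$optimal_trees)))
  }
  cat(sprintf("collapse rule: %s; %d replicate(s); seed %s\n",
              x$collapse_rule, nrow(x$replicate_log),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Heuristic parsimony search
#'
#' Random addition sequences followed by branch swapping; the pooled optima
#' are swapped to closure, collapsed under the configured rule, and
#' deduplicated by topology.
#'
#' @param m a [character_matrix].
#' @param config a [search_config()].
#' @param seed integer seed (overrides `config$seed`).
#' @param weights optional per-character weights (used by the ratchet).
#' @return an object of class `mp_search`: `best_score`, `optimal_trees`
#'   (collapsed), `binary_trees` (uncollapsed representatives),
#'   `replicate_log`, `seed`, `config`.
#' @export
heuristic_search <- function(m, config = search_config(), seed = config$seed,
                             weights = NULL) {
  ctx <- objective_ctx(m, config, weights)
  n <- length(m$taxa)
  if (n < 4L) mp_stop("size_error", "search requires >= 4 taxa")
  best <- Inf
  pool <- list()
  hashes <- character(0)
  log_scores <- numeric(config$replicates)
  with_seed(seed, {
    for (rep in seq_len(config$replicates)) {
      ord <- sample.int(n)
      start <- ras_tree_cpp(ord, ctx$masks, ctx$weights, ctx$iw, ctx$k,
                            ctx$minsteps)
      cl <- climb(start, ctx, config)
      log_scores[rep] <- cl$score
      if (cl$score < best - EPS) {
        best <- cl$score
        pool <- list()
        hashes <- character(0)
      }
      if (cl$score <= best + EPS) {
        for (e in cl$edges) {
          h <- pool_hash(e, ctx, config)
          if (h %in% hashes || length(pool) >= config$maxtrees) next
          hashes <- c(hashes, h)
          pool[[length(pool) + 1L]] <- e
        }
      }
    }
  })
  cls <- closure(pool, hashes, best, ctx, config)
  finalize_result(m, config, cls$best,
                  cls$pool, data.frame(replicate = seq_len(config$replicates),
                                       score = log_scores),
                  seed, ctx)
}

#' Exact search by branch and bound
#'
#' Provably returns all minimum-length binary trees for up to 12 taxa.
#' Taxa are added in matrix order; partial trees are pruned with the bound
#' "partial length + number of states only observed in unplaced taxa".
#'
#' @param m a [character_matrix].
#' @param taxa optional subset of taxa to analyse (default: all).
#' @param collapse collapse rule applied to the optima.
#' @return an `mp_search` object.
#' @export
branch_and_bound <- function(m, taxa = m$taxa,
                             collapse = c("min_length_zero", "none")) {
  collapse <- match.arg(collapse)
  msub <- if (length(taxa) == length(m$taxa) &&
              all(taxa == m$taxa)) m else subset_taxa(m, taxa)
  n <- length(msub$taxa)
  if (n > 12L) mp_stop("size_error", "branch and bound supports at most 12 taxa")
  if (n < 4L) mp_stop("size_error", "branch and bound requires >= 4 taxa")
  cfg <- search_config(collapse = collapse)
  ctx <- objective_ctx(msub, cfg)
  masks <- ctx$masks
  nc <- ncol(masks)
  # per character: states observed determinately in taxa > j (suffix sets);
  # each state absent from the placed taxa costs at least one extra step
  det_state <- function(i, ch) {
    tok <- msub$cells[i, ch]
    if (grepl("^[0-9]$", tok)) as.integer(tok) else NA_integer_
  }
  state_sets <- lapply(seq_len(nc), function(ch)
    vapply(seq_len(n), det_state, integer(1L), ch = ch))
  bound_extra <- function(kplaced) {
    extra <- 0L
    for (ch in seq_len(nc)) {
      s <- state_sets[[ch]]
      placed <- unique(s[seq_len(kplaced)])
      rest <- unique(s[(kplaced + 1L):n])
      extra <- extra + length(setdiff(rest[!is.na(rest)], placed))
    }
    extra
  }
  best <- Inf
  optima <- list()
  rec <- function(edges, kplaced) {
    len <- score_edge_partial(edges, masks, n)
    if (kplaced == n) {
      if (len < best - EPS) {
        best <<- len
        optima <<- list(edges)
      } else if (len <= best + EPS) {
        optima[[length(optima) + 1L]] <<- edges
      }
      return(invisible())
    }
    if (len + bound_extra(kplaced) > best + EPS) return(invisible())
    newint <- n + kplaced - 1L
    t <- kplaced + 1L
    for (r in seq_len(nrow(edges))) {
      e2 <- rbind(edges[-r, , drop = FALSE],
                  c(edges[r, 1L], newint),
                  c(newint, edges[r, 2L]),
                  c(newint, t))
      rec(e2, t)
    }
  }
  start <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
  rec(start, 3L)
  pool <- lapply(optima, function(ed) {
    adj <- vector("list", 2L * n - 2L)
    for (r in seq_len(nrow(ed))) {
      a <- ed[r, 1L]; b <- ed[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    phylo_from_adj(adj, msub$taxa)$edge
  })
  # dedupe (enumeration is already unique, but collapsing may merge)
  finalize_result(msub, cfg, best, pool,
                  data.frame(replicate = 1L, score = best), NULL, ctx)
}

# score a partial tree given as an undirected edge list over tips 1..k
score_edge_partial <- function(edges, masks, nTip) {
  M <- 2L * nTip - 2L
  # reuse the compiled scorer by routing through an adjacency canonicaliser:
  # tips present are exactly those of degree >= 1
  adjm <- matrix(0L, nrow(edges), 2L)
  adjm[] <- edges
  counts <- fitch_counts_partial_cpp(adjm, nTip, masks)
  sum(counts)
}

#' Parsimony ratchet search
#'
#' Alternates branch swapping under perturbed character weights (a seeded
#' fraction of characters upweighted) with swapping under the original
#' weights, starting from the plain heuristic result; the returned score is
#' never worse than the plain search from the same seed.
#'
#' @param m a [character_matrix].
#' @param config a [search_config()] with `ratchet` set (defaults applied
#'   when missing: 20 iterations, perturb 0.25, multiplier 2).
#' @param seed integer seed.
#' @return an `mp_search` object.
#' @export
ratchet_search <- function(m, config = search_config(ratchet = list(
  iterations = 20L, perturb_fraction = 0.25, weight_multiplier = 2)),
  seed = config$seed) {
  if (is.null(config$ratchet))
    config$ratchet <- list(iterations = 20L, perturb_fraction = 0.25,
                           weight_multiplier = 2)
  rt <- config$ratchet
  ctx <- objective_ctx(m, config)
  n <- length(m$taxa)
  nc <- ncol(ctx$masks)
  base_cfg <- config
  base_cfg$ratchet <- NULL
  plain_cfg <- base_cfg
  plain_cfg$replicates <- max(1L, min(base_cfg$replicates, 20L))
  res <- heuristic_search(m, plain_cfg, seed = seed)
  best <- res$best_score
  pool <- lapply(res$binary_trees, `[[`, "edge")
  hashes <- vapply(pool, pool_hash, character(1L), ctx = ctx, cfg = config)
  with_seed(if (is.null(seed)) NULL else seed + 1L, {
    current <- pool[[1L]]
    for (it in seq_len(rt$iterations)) {
      nup <- round(rt$perturb_fraction * nc)
      w <- rep(1, nc)
      if (nup > 0L) w[sample.int(nc, nup)] <- rt$weight_multiplier
      # swap under perturbed weights
      ctx_p <- ctx
      ctx_p$weights <- w
      cl_p <- climb(current, ctx_p, base_cfg)
      # re-optimise under original weights
      cl <- climb(cl_p$edges[[1L]], ctx, base_cfg)
      if (cl$score < best - EPS) {
        best <- cl$score
        pool <- list()
        hashes <- character(0)
      }
      if (cl$score <= best + EPS) {
        for (e in cl$edges) {
          h <- pool_hash(e, ctx, config)
          if (h %in% hashes || length(pool) >= config$maxtrees) next
          hashes <- c(hashes, h)
          pool[[length(pool) + 1L]] <- e
        }
      }
      current <- cl$edges[[1L]]
    }
  })
  finalize_result(m, config, best, pool, res$replicate_log, seed, ctx)
}

#' Implied-weighting search
#'
#' Heuristic search maximising the Goloboff fit `F = sum k/(k+e_i)`; the
#' optimal trees are the fit-maximal trees after collapsing.
#'
#' @param m a [character_matrix].
#' @param k concavity constant (> 0).
#' @param config a [search_config()]; its objective/k are overridden.
#' @param seed integer seed.
#' @return an `mp_search` object with `best_fit` on the maximisation scale.
#' @export
iw_search <- function(m, k = 3, config = search_config(), seed = config$seed) {
  if (k <= 0) mp_stop("concavity_error", "concavity k must be > 0")
  config$objective <- "implied_weighting"
  config$k <- k
  heuristic_search(m, config, seed = seed)
}
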