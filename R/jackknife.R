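# Character jackknife: each character is independently deleted with a fixed
# probability, the reduced matrix is re-searched, and each replicate
# contributes the bipartitions common to all of its optimal trees. Support
# is the percentage of replicates containing a bipartition.

#' Jackknife support
#'
#' @param m a [character_matrix].
#' @param p_del per-character deletion probability (default 0.36, the
#'   common independent-removal convention close to 1/e; the source
#'   analyses do not state theirs).
#' @param reps number of replicates (the published analyses used 1,000;
#'   desk-scale runs use fewer).
#' @param config [search_config()] for the per-replicate searches; the
#'   default uses a reduced budget (20 addition replicates, TBR, small tree
#'   pool), standard practice for resampling: a replicate contributes only
#'   the strict-consensus splits of its optima, which saturate long before
#'   the full optimum plateau is enumerated.
#' @param seed integer seed for the whole resampling run.
#' @return object of class `support_table`: data frame with `split`
#'   (canonical key), `taxa` (display string) and `support` (percent), with
#'   attributes `reps`, `p_del`, `seed`, `redrawn` (count of replicates
#'   redrawn because every character was deleted).
#' @export
jackknife <- function(m, p_del = 0.36, reps = 1000L,
                      config = search_config(replicates = 20L, hold = 10L,
                                             maxtrees = 25L),
                      seed = NULL) {
  stopifnot(p_del >= 0, p_del < 1, reps >= 1L)
  nc <- ncol(m$cells)
  tally <- new.env(parent = emptyenv())
  redrawn <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      repeat {
        keep <- stats::runif(nc) >= p_del
        if (any(keep)) break
        redrawn <- redrawn + 1L
      }
      msub <- subset_characters(m, which(keep))
      rep_seed <- sample.int(.Machine$integer.max, 1L)
      res <- heuristic_search(msub, config, seed = rep_seed)
      splits <- Reduce(intersect, lapply(res$optimal_trees, bipartitions))
      for (s in splits) {
        cur <- if (is.null(tally[[s]])) 0L else tally[[s]]
        tally[[s]] <- cur + 1L
      }
    }
  })
  keys <- ls(tally)
  support <- vapply(keys, function(k) 100 * tally[[k]] / reps, numeric(1L))
  ord <- order(-support, keys)
  out <- data.frame(split = keys[ord],
                    taxa = gsub("|", ", ", keys[ord], fixed = TRUE),
                    support = support[ord],
                    row.names = NULL)
  structure(out, class = c("support_table", "data.frame"),
            reps = reps, p_del = p_del, seed = seed, redrawn = redrawn)
}

#' Annotate a tree with support values
#'
#' Labels each internal node whose bipartition reaches the threshold with
#' its support percentage; other internal nodes get blank labels.
#'
#' @param tree a `phylo` on the same taxon set as the support table.
#' @param support a `support_table` (from [jackknife()]).
#' @param threshold minimum percentage for a label (default 50).
#' @return the tree with `node.label` set.
#' @export
annotate_support <- function(tree, support, threshold = 50) {
  n <- length(tree$tip.label)
  all_taxa <- sort(tree$tip.label)
  sup_taxa <- unique(unlist(strsplit(support$split, "|", fixed = TRUE)))
  if (!all(sup_taxa %in% all_taxa))
    mp_stop("leaf_set_error",
            "support table refers to taxa absent from the tree")
  tree2 <- stats::reorder(tree, "postorder")
  M <- n + tree2$Nnode
  below <- vector("list", M)
  for (i in seq_len(n)) below[[i]] <- tree2$tip.label[i]
  for (r in seq_len(nrow(tree2$edge))) {
    p <- tree2$edge[r, 1L]; c <- tree2$edge[r, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  labels <- rep("", tree2$Nnode)
  lookup <- stats::setNames(support$support, support$split)
  for (node in (n + 1L):M) {
    side <- below[[node]]
    if (min(length(side), n - length(side)) < 2L) next
    key <- split_key(side, tree2$tip.label)
    val <- lookup[key]
    if (!is.na(val) && val >= threshold)
      labels[node - n] <- as.character(round(val))
  }
  tree2$node.label <- labels
  tree2
}

#' Write a support table as TSV
#' @param support a `support_table`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_support_tsv <- function(support, path) {
  utils::write.table(as.data.frame(support), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
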