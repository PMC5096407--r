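#!/usr/bin/env Rscript
# Implied-weighting searches over a range of concavity constants. Character
# fits are k/(k+e); the search maximises the total fit, downweighting
# homoplastic characters.

suppressPackageStartupMessages(library(morphparsimony))
dir.create("results", showWarnings = FALSE)
seed <- 2027L

m <- load_fixture("table1")
rows <- list()
for (k in 3:8) {
  res <- iw_search(m, k = k, search_config(replicates = 100L),
                   seed = seed + k)
  tls <- vapply(res$binary_trees, function(t) tree_length(m, t), numeric(1L))
  rows[[length(rows) + 1L]] <- data.frame(
    k = k, n_optimal_trees = length(res$optimal_trees),
    best_fit = res$best_fit, tree_length = paste(unique(tls), collapse = "/"))
  writeLines(vapply(res$optimal_trees, write_newick, character(1L)),
             sprintf("results/iw_k%d.nwk", k))
  message(sprintf("k = %d: %d fit-optimal trees, F = %.4f, TL %s",
                  k, length(res$optimal_trees), res$best_fit,
                  rows[[length(rows)]]$tree_length))
}
tab <- do.call(rbind, rows)
utils::write.table(tab, "results/implied_weighting.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# The k = 7-8 optima coincide with a subset of the equal-weights MPTs; the
# k = 3-6 optimum is a slightly longer (TL 70) tree family whose homoplasy
# is spread across more characters, which the concave fit prefers.
write_run_report(run_report(
  command = "implied_weighting",
  config = list(k_range = "3..8", replicates = 100L), seed = seed,
  inputs = list(matrix = system.file("extdata", "table1.csv",
                                     package = "morphparsimony")),
  outputs = list(table = "results/implied_weighting.tsv"),
  warnings = "fit-optimal tree counts depend on the branch-collapsing convention"),
  "results/02_implied_weighting_report.json")
message("wrote results/implied_weighting.tsv and iw_k*.nwk")
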