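#!/usr/bin/env Rscript
# Aggregate report: combined macro table across scenarios, per-class PR
# curves, and 2-D t-SNE projections of the test-set embeddings.
# Requires 04_scenarios.R. Writes results/summary_table.txt,
# results/pr_curves.csv, results/tsne_coordinates.csv.

library(medgest)

scen_dir <- "results/scenarios"
summary_lines <- c()
pr_rows <- list()
tsne_rows <- list()

for (sid in 1:3) {
  nm <- paste0("scenario_", sid)
  metrics <- data.table::fread(file.path(scen_dir, paste0(nm, "_metrics.csv")))
  macro <- metrics[metrics$class == "macro", ]
  summary_lines <- c(summary_lines, sprintf(
    "Scenario %d: macro precision %.2f, recall %.2f, F1 %.2f (n test = %d)",
    sid, macro$precision, macro$recall, macro$f1, macro$support))

  scores <- data.table::fread(file.path(scen_dir, paste0(nm, "_test_scores.csv")))
  classes <- setdiff(names(scores), "true")
  for (cl in classes) {
    if (length(unique(scores$true == cl)) < 2) next
    curve <- pr_curve(scores[[cl]], scores$true, cl)
    pr_rows[[paste(nm, cl)]] <- data.frame(scenario = sid, class = cl, curve)
  }

  emb <- data.table::fread(file.path(scen_dir, paste0(nm, "_test_embeddings.csv")))
  X <- as.matrix(emb[, -1])
  perp <- min(10, floor((nrow(X) - 1) / 3))
  Y <- project_embeddings(X, seed = sid, perplexity = perp)
  tsne_rows[[nm]] <- data.frame(scenario = sid, label = emb$label,
                                tsne1 = Y[, 1], tsne2 = Y[, 2])
}

writeLines(summary_lines, "results/summary_table.txt")
data.table::fwrite(do.call(rbind, pr_rows), "results/pr_curves.csv")
data.table::fwrite(do.call(rbind, tsne_rows), "results/tsne_coordinates.csv")
cat(paste(summary_lines, collapse = "\n"), "\n")
cat("Wrote results/summary_table.txt, results/pr_curves.csv,",
    "results/tsne_coordinates.csv\n")
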