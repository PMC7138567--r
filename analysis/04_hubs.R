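#!/usr/bin/env Rscript
# Stage 4: hub genes in the non-preserved modules.
#
# Five hub scores per gene on the discovery cohort's weighted module graph
# (module membership, betweenness, closeness, PageRank, Kleinberg), with
# significance from 1,000 random relabellings of the adjacency gene labels;
# a gene is a significant hub when any score's p-value is below 0.01. Also
# exports the Figure-style edge list of the module above an adjacency
# cutoff.

library(preservenet)

seed <- 20260927L
data_dir <- "results/data"
net_dir <- "results/network"
pres_dir <- "results/preservation"
out <- "results/hubs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (dir_tag in c("ab", "ba")) {
  cohort <- if (dir_tag == "ab") "a" else "b"
  tab <- read.delim(file.path(pres_dir, sprintf("preservation_%s.tsv", dir_tag)))
  np <- tab$module[tab$nonpreserved]
  if (length(np) == 0) {
    cat(sprintf("[%s] no non-preserved modules; nothing to score\n", dir_tag))
    next
  }
  expr <- read_expression_tsv(file.path(data_dir, sprintf("cohort_%s.tsv", cohort)))
  power <- jsonlite::read_json(
    file.path(net_dir, sprintf("soft_threshold_%s.json", cohort)))$chosen_power
  am <- adjacency(correlation_matrix(expr), power)
  mods <- read.delim(file.path(net_dir, sprintf("modules_%s.tsv", cohort)))
  for (lab in np) {
    genes <- mods$gene_id[mods$module == lab]
    g <- module_graph(am, genes)
    eig <- module_eigengene(expr, genes)
    scores <- hub_scores(g, expr, eig)
    scores <- hub_permutation_test(
      scores, n_perm = 1000,
      seed = child_seed(seed, paste0("hubs_", dir_tag, "_", lab)))
    write_hub_table_tsv(scores,
                        file.path(out, sprintf("hubs_%s_%s.tsv", dir_tag, lab)))
    hubs <- significant_hubs(scores)
    cat(sprintf("[%s] module %s (%d genes): %d significant hubs: %s\n",
                dir_tag, lab, length(genes), length(hubs),
                paste(utils::head(hubs, 10), collapse = ", ")))
    # adjacency scale depends strongly on the soft power; export the top 1%
    # of within-module edges
    w <- am[genes, genes]
    cutoff <- unname(stats::quantile(w[upper.tri(w)], 0.99))
    exp_out <- export_threshold_graph(
      am, genes, cutoff = cutoff,
      path = file.path(out, sprintf("edges_%s_%s.tsv", dir_tag, lab)))
    cat(sprintf("[%s] module %s export at adjacency > %.3g: %s\n",
                dir_tag, lab, cutoff, exp_out$summary))
  }
}
cat(sprintf("Artifacts written under %s\n", out))
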