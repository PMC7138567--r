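#!/usr/bin/env Rscript
# Stage 3: module preservation testing between the cohorts, both directions.
#
# Seven preservation statistics per module, permutation null from random
# same-size gene sets of the shared universe (1,000 permutations here;
# the conventional 10,000 changes only the attainable p-value floor),
# alternative "less": a module is non-preserved when all seven p-values
# fall below 0.05.

library(preservenet)

seed <- 20260927L
data_dir <- "results/data"
net_dir <- "results/network"
out <- "results/preservation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
n_perm <- 1000

nets <- lapply(c(a = "a", b = "b"), function(cohort) {
  expr <- read_expression_tsv(file.path(data_dir, sprintf("cohort_%s.tsv", cohort)))
  power <- jsonlite::read_json(
    file.path(net_dir, sprintf("soft_threshold_%s.json", cohort)))$chosen_power
  mods <- read.delim(file.path(net_dir, sprintf("modules_%s.tsv", cohort)))
  assign <- structure(stats::setNames(mods$module, mods$gene_id),
                      class = "module_assignment")
  list(expr = expr,
       adjacency = adjacency(correlation_matrix(expr), power),
       assignment = assign)
})

for (dir_tag in c("ab", "ba")) {
  disc <- if (dir_tag == "ab") nets$a else nets$b
  tst <- if (dir_tag == "ab") nets$b else nets$a
  res <- preservation_permutation_test(
    disc, tst, disc$assignment, n_perm = n_perm,
    seed = child_seed(seed, paste0("preserve_", dir_tag)))
  tab <- preservation_table(res)
  write.table(tab, file.path(out, sprintf("preservation_%s.tsv", dir_tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_preservation_json(res,
                          file.path(out, sprintf("preservation_%s.json", dir_tag)))
  np <- classify_nonpreserved(res)
  cat(sprintf("[%s] modules tested: %d; non-preserved: %s\n", dir_tag,
              nrow(tab), if (length(np)) paste(np, collapse = ", ") else "none"))
  print(tab[, c("module", "size", "max_p_printed", "nonpreserved")],
        row.names = FALSE)
}
cat(sprintf("Artifacts written under %s\n", out))
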