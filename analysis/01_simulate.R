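#!/usr/bin/env Rscript
# Stage 1: generate the two-cohort study data with planted ground truth.
#
# Produces a pair of blood-style expression cohorts sharing an 800-gene
# universe: four co-expression modules (320/100/90/120 genes) driven by
# latent factors, one planted hub per module (loading 0.95 vs 0.5-0.8), and
# the 120-gene module's correlation structure destroyed in cohort B. Also
# writes the matching annotation fixtures: a gene-set library enriched for
# the planted modules, a "GWAS" gene list concentrated in the non-preserved
# module, and gene-SNP / SNP-miRNA tables with planted passing rows and
# boundary decoys.

library(preservenet)

seed <- 20260927L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = child_seed(seed, "data"))
pair <- generate_cohort_pair(cfg)

write_expression_tsv(pair$cohort_a, file.path(out, "cohort_a.tsv"))
write_expression_tsv(pair$cohort_b, file.path(out, "cohort_b.tsv"))
write_ground_truth_json(pair$truth, file.path(out, "ground_truth.json"))

lib <- generate_gene_set_library(pair$truth, n_sets = 20,
                                 enriched_fraction = 0.8,
                                 seed = child_seed(seed, "gmt"))
write_gmt(lib, file.path(out, "gene_sets.gmt"))
writeLines(pair$truth$gwas_genes, file.path(out, "gwas_genes.txt"))
writeLines(pair$truth$disease_mirnas, file.path(out, "disease_mirnas.txt"))

vt <- generate_variant_tables(pair$truth, seed = child_seed(seed, "variants"))
write.table(vt$gene_snp, file.path(out, "gene_snp.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(vt$snp_mirna, file.path(out, "snp_mirna.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sizes <- table(pair$truth$true_assignment)
cat(sprintf("Simulated %d genes x (%d + %d) samples.\n", cfg$n_genes,
            cfg$n_samples_a, cfg$n_samples_b))
cat("Planted module sizes:\n")
print(sizes)
cat(sprintf("Non-preserved in cohort B: %s (%d genes)\n",
            pair$truth$nonpreserved_labels,
            sizes[pair$truth$nonpreserved_labels]))
cat(sprintf("Planted hubs: %s\n",
            paste(unlist(pair$truth$hub_genes), collapse = ", ")))
cat(sprintf("Artifacts written under %s\n", out))
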