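#' Read a GMT gene-set library
#'
#' GMT is tab-separated: set name, description, then member gene IDs.
#'
#' @param path GMT file path.
#' @param source source tag (`"GO"`, `"KEGG"`, `"TF"` or `"synthetic"`).
#' @return a `gene_set_library` (list with `sets`, `source`).
#' @export
read_gmt <- function(path, source = "synthetic") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) config_error("malformed GMT record: %s", ln)
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  structure(list(sets = sets, source = source), class = "gene_set_library")
}

#' Write a gene-set library as GMT
#' @param lib a `gene_set_library` (or named list of gene vectors).
#' @param path output path.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path, description = "na") {
  sets <- if (inherits(lib, "gene_set_library")) lib$sets else lib
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Hypergeometric over-representation test against a gene-set library
#'
#' For each set, the one-sided (upper tail) hypergeometric p-value of the
#' overlap between the query and the in-background portion of the set, given
#' the background universe. Query genes outside the background are dropped
#' with a warning. Overlap is reported as `"k/K"` with `K` the in-background
#' set size.
#'
#' @param query gene list (e.g. a module's genes).
#' @param lib a `gene_set_library`.
#' @param background the background gene universe (non-empty).
#' @param fdr add a Benjamini-Hochberg adjusted column (default TRUE).
#' @return data.frame sorted by p-value: `set`, `overlap_count`, `set_size`,
#'   `p_value`, `overlap` ("k/K"), optional `fdr`.
#' @export
overrepresentation_test <- function(query, lib, background, fdr = TRUE) {
  if (length(background) == 0) config_error("background universe is empty")
  background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warning(sprintf("%d query gene(s) outside background dropped", length(outside)))
    query <- intersect(query, background)
  }
  query <- unique(query)
  N <- length(background)
  n_q <- length(query)
  rows <- lapply(names(lib$sets), function(nm) {
    set_bg <- intersect(lib$sets[[nm]], background)
    K <- length(set_bg)
    k <- length(intersect(query, set_bg))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n_q, lower.tail = FALSE)
    data.frame(set = nm, overlap_count = k, set_size = K, p_value = p,
               overlap = sprintf("%d/%d", k, K))
  })
  out <- do.call(rbind, rows)
  if (fdr) out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$set), , drop = FALSE]
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact p-value (two-sided by the probability-mass definition: tables whose
#' hypergeometric probability does not exceed the observed one), conditional
#' maximum-likelihood odds ratio and 95% confidence interval by inversion of
#' the exact test — the conventions of `stats::fisher.test`. With a zero
#' cell the conditional MLE may be 0 or infinite and the CI one-sided; no
#' error is raised.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `matrix(c(a, c, b, d), 2)` i.e. rows (a, b) and (c, d).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return list of class `fisher_2x2`: `table`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `alternative`.
#' @export
fisher_2x2 <- function(a, b, c, d,
                       alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    config_error("cell counts must be non-negative integers")
  if (sum(cells) == 0) config_error("at least one positive margin required")
  tab <- matrix(as.integer(c(a, c, b, d)), nrow = 2)
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alternative]
  ft <- stats::fisher.test(tab, alternative = alt)
  structure(list(table = tab,
                 odds_ratio = unname(ft$estimate),
                 ci_low = ft$conf.int[1],
                 ci_high = ft$conf.int[2],
                 p_value = ft$p.value,
                 alternative = alternative),
            class = "fisher_2x2")
}

#' @export
print.fisher_2x2 <- function(x, ...) {
  cat(sprintf("Fisher exact test (%s): OR = %.3g, 95%% CI %.3g~%.3g, p = %.4g\n",
              x$alternative, x$odds_ratio, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' GWAS-gene enrichment in non-preserved modules
#'
#' Builds the 2x2 table (gene in a non-preserved module?) x (gene in the
#' GWAS list?) over all genes of the assignment and applies a two-sided
#' Fisher exact test. Unassigned genes count in the preserved stratum by
#' default (the contrast is non-preserved modules against everything else).
#'
#' @param assign a `module_assignment`.
#' @param nonpreserved character vector of non-preserved module labels
#'   (non-empty).
#' @param gwas GWAS gene list (non-empty).
#' @param include_unassigned count unassigned genes in the preserved stratum
#'   (default TRUE); if FALSE they are excluded from the table.
#' @return a `fisher_2x2` result.
#' @export
gwas_module_enrichment <- function(assign, nonpreserved, gwas,
                                   include_unassigned = TRUE) {
  if (length(nonpreserved) == 0)
    config_error("no non-preserved modules: skip the GWAS enrichment test")
  if (length(gwas) == 0) config_error("empty GWAS gene list")
  genes <- names(assign)
  if (!include_unassigned) genes <- genes[assign[genes] != "unassigned"]
  in_np <- assign[genes] %in% nonpreserved
  in_gwas <- genes %in% gwas
  fisher_2x2(sum(in_np & in_gwas), sum(in_np & !in_gwas),
             sum(!in_np & in_gwas), sum(!in_np & !in_gwas),
             alternative = "two_sided")
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    config_error("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", "))
}

#' Filtered SNP-to-miRNA join for a module
#'
#' Keeps gene-SNP rows whose gene belongs to the module, whose eQTL p-value
#' is strictly below `p_thresh` and whose frequency is strictly above
#' `freq_thresh`; joins the surviving SNPs to the SNP-miRNA table and keeps
#' rows whose miRNA is in the disease list. Output rows are unique
#' (gene, snp, mirna) triples in deterministic order.
#'
#' @param module_genes gene list.
#' @param gene_snp data.frame with columns `gene`, `snp_id`, `p_value`,
#'   `frequency`.
#' @param snp_mirna data.frame with columns `snp_id`, `mirna_id`.
#' @param disease_mirnas disease-associated miRNA identifiers.
#' @param p_thresh eQTL p-value threshold (default 1e-4, strict `<`).
#' @param freq_thresh allele-frequency threshold (default 0.10, strict `>`).
#' @return data.frame of class `snp_hit_table`: `gene`, `snp_id`, `mirna_id`.
#' @export
snp_mirna_filter_join <- function(module_genes, gene_snp, snp_mirna,
                                  disease_mirnas, p_thresh = 1e-4,
                                  freq_thresh = 0.10) {
  check_columns(gene_snp, c("gene", "snp_id", "p_value", "frequency"), "gene_snp")
  check_columns(snp_mirna, c("snp_id", "mirna_id"), "snp_mirna")
  keep <- gene_snp$gene %in% module_genes &
    gene_snp$p_value < p_thresh &
    gene_snp$frequency > freq_thresh
  hits <- merge(gene_snp[keep, c("gene", "snp_id")], snp_mirna, by = "snp_id")
  hits <- hits[hits$mirna_id %in% disease_mirnas,
               c("gene", "snp_id", "mirna_id"), drop = FALSE]
  hits <- unique(hits)
  hits <- hits[order(hits$gene, hits$snp_id, hits$mirna_id), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("snp_hit_table", "data.frame")
  hits
}

#' Overlap of SNP hits between two diseases
#'
#' Intersects two filtered SNP hit tables on `snp_id` and reports the sizes
#' of both sets, the intersection, and the shared SNPs with the genes they
#' map to in each table.
#'
#' @param hits_a,hits_b `snp_hit_table`s from [snp_mirna_filter_join()].
#' @return list: `n_a`, `n_b`, `n_shared`, `shared` (data.frame: `snp_id`,
#'   `genes_a`, `genes_b`).
#' @export
cross_disease_overlap <- function(hits_a, hits_b) {
  snps_a <- unique(hits_a$snp_id)
  snps_b <- unique(hits_b$snp_id)
  shared <- sort(intersect(snps_a, snps_b))
  detail <- data.frame(
    snp_id = shared,
    genes_a = vapply(shared, function(s)
      paste(sort(unique(hits_a$gene[hits_a$snp_id == s])), collapse = ","),
      character(1)),
    genes_b = vapply(shared, function(s)
      paste(sort(unique(hits_b$gene[hits_b$snp_id == s])), collapse = ","),
      character(1)),
    row.names = NULL
  )
  list(n_a = length(snps_a), n_b = length(snps_b), n_shared = length(shared),
       shared = detail)
}
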