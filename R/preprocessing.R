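#' Collapse a probe-level matrix to one row per gene by maximal MAD
#'
#' When several probes map to one gene, the probe with the highest median
#' absolute deviation across samples is kept (MAD here is unscaled,
#' `median(|x - median(x)|)` — the 1.4826 consistency constant does not
#' change the argmax and is omitted for reproducibility). Ties are broken by
#' the lexicographically smallest probe ID so runs are reproducible.
#'
#' @param values probes x samples numeric matrix with probe IDs as rownames.
#' @param probe_gene_map data.frame with columns `probe_id`, `gene_id`.
#'   Probes without a mapping entry are dropped.
#' @return genes x samples numeric matrix, one row per gene, rownames the
#'   gene IDs, rows ordered by first appearance of each gene in the probe
#'   order. The chosen probe IDs are attached as attribute `probe_id`.
#' @export
collapse_probes_by_mad <- function(values, probe_gene_map) {
  if (!is.matrix(values) || nrow(values) == 0)
    config_error("probe matrix is empty")
  if (is.null(rownames(values)))
    config_error("probe matrix must carry probe IDs as rownames")
  if (!all(c("probe_id", "gene_id") %in% names(probe_gene_map)))
    config_error("probe_gene_map needs columns 'probe_id' and 'gene_id'")
  map <- stats::setNames(as.character(probe_gene_map$gene_id),
                         as.character(probe_gene_map$probe_id))
  keep <- rownames(values) %in% names(map)
  values <- values[keep, , drop = FALSE]
  if (nrow(values) == 0) config_error("no probe has a gene mapping")
  gene <- map[rownames(values)]
  mad_unscaled <- apply(values, 1, function(x) stats::median(abs(x - stats::median(x))))
  ord <- order(match(gene, unique(gene)), -mad_unscaled, rownames(values))
  first <- !duplicated(gene[ord])
  chosen <- ord[first]
  out <- values[chosen, , drop = FALSE]
  probes <- rownames(out)
  rownames(out) <- unname(gene[chosen])
  attr(out, "probe_id") <- stats::setNames(probes, rownames(out))
  out
}

#' Remove the lowest-expressed fraction of genes
#'
#' Drops `floor(fraction * n_genes)` genes with the lowest mean expression
#' across all samples ("average expression" read as the arithmetic mean).
#' Ties at the cut are broken by removing the lexicographically smallest
#' gene ID first. The output preserves the input gene order.
#'
#' @param expr genes x samples numeric matrix with gene IDs as rownames.
#' @param fraction fraction to remove, in \[0, 1).
#' @return the filtered matrix.
#' @export
filter_low_expression <- function(expr, fraction = 0.05) {
  if (fraction < 0 || fraction >= 1) config_error("fraction must lie in [0, 1)")
  n_remove <- floor(fraction * nrow(expr))
  if (n_remove == 0) return(expr)
  means <- rowMeans(expr)
  drop_idx <- order(means, rownames(expr))[seq_len(n_remove)]
  expr[-drop_idx, , drop = FALSE]
}

#' Read a probe matrix and its probe-to-gene map from TSV
#'
#' @param values_path TSV with first column `probe_id`, remaining columns
#'   samples.
#' @param map_path two-column TSV (`probe_id`, `gene_id`).
#' @return list with `values` (matrix) and `probe_gene_map` (data.frame).
#' @export
read_probe_matrix <- function(values_path, map_path) {
  df <- utils::read.delim(values_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id")
    config_error("expected first column 'probe_id' in %s", values_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  storage.mode(m) <- "double"
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  list(values = m, probe_gene_map = map)
}
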