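#' Construct a module graph from an adjacency matrix
#'
#' @param am full adjacency matrix.
#' @param genes module gene IDs (>= 3).
#' @param edge_interpretation `"weight_as_cost"` (default; adjacency values
#'   are passed directly as edge weights, which shortest-path centralities
#'   treat as traversal costs — the default behavior of the igraph library
#'   when weights are supplied) or `"weight_as_strength"` (path costs are
#'   `1/weight`).
#' @return list of class `module_graph`: `genes`, `weights` (symmetric
#'   matrix, zero diagonal), `edge_interpretation`.
#' @export
module_graph <- function(am, genes,
                         edge_interpretation = c("weight_as_cost",
                                                 "weight_as_strength")) {
  edge_interpretation <- match.arg(edge_interpretation)
  if (length(genes) < 3) config_error("a module graph needs >= 3 genes")
  missing <- setdiff(genes, rownames(am))
  if (length(missing) > 0)
    config_error("genes missing from adjacency: %s",
                 paste(utils::head(missing, 5), collapse = ", "))
  w <- am[genes, genes]
  diag(w) <- 0
  if (any(w < 0)) config_error("adjacency weights must be non-negative")
  structure(list(genes = genes, weights = w,
                 edge_interpretation = edge_interpretation),
            class = "module_graph")
}

to_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Five hub scores for every gene of a module
#'
#' Scores are computed on the full weighted module graph (edges of weight 0
#' are absent), unnormalized: module membership `mm(i)` is the correlation
#' of gene i's expression with the module eigengene; betweenness is Brandes
#' shortest-path betweenness; closeness is `1 / sum_j dist(i, j)` (computed
#' per connected component, with a warning, when the graph is disconnected);
#' PageRank uses damping 0.85 on weights as strengths (scores sum to 1 over
#' the module); the Kleinberg hub score is the principal eigenvector of the
#' symmetric weight matrix scaled to maximum 1. Shortest-path metrics use
#' edge costs per the graph's `edge_interpretation`.
#'
#' @param g a [module_graph()].
#' @param expr genes x samples expression matrix (for module membership).
#' @param eig the module's [module_eigengene()].
#' @return data.frame of class `hub_score_table`: `gene_id`, `mm`,
#'   `betweenness`, `closeness`, `pagerank`, `kleinberg`; attribute
#'   `edge_interpretation`.
#' @export
hub_scores <- function(g, expr, eig) {
  stopifnot(inherits(g, "module_graph"))
  ig <- to_igraph(g)
  ew <- igraph::E(ig)$weight
  costs <- if (g$edge_interpretation == "weight_as_cost") ew else 1 / ew
  mm <- as.numeric(stats::cor(t(expr[g$genes, , drop = FALSE]), eig$values))
  # igraph warns about near-zero edge costs (routine for high soft powers);
  # disconnectedness is re-reported below as this package's own warning
  btw <- suppressWarnings(igraph::betweenness(ig, weights = costs,
                                              normalized = FALSE))
  n_comp <- igraph::components(ig)$no
  if (n_comp > 1)
    warning("module graph is disconnected: closeness computed per component")
  cls <- suppressWarnings(igraph::closeness(ig, weights = costs,
                                            normalized = FALSE))
  pr <- igraph::page_rank(ig, damping = 0.85, weights = ew)$vector
  es <- eigen(g$weights, symmetric = TRUE)
  kv <- abs(es$vectors[, which.max(es$values)])
  kleinberg <- if (max(kv) > 0) kv / max(kv) else kv
  out <- data.frame(gene_id = g$genes, mm = mm,
                    betweenness = as.numeric(btw),
                    closeness = as.numeric(cls),
                    pagerank = as.numeric(pr),
                    kleinberg = kleinberg,
                    row.names = NULL)
  attr(out, "edge_interpretation") <- g$edge_interpretation
  class(out) <- c("hub_score_table", "data.frame")
  out
}

hub_score_names <- c("mm", "betweenness", "closeness", "pagerank", "kleinberg")

#' Label-permutation significance of hub scores
#'
#' The null model randomly relabels the genes on the module's adjacency
#' matrix and recomputes every hub score: because relabelling the matrix
#' permutes the score vector without changing its values, each permutation
#' re-reads every gene's score at its label's new position. The p-value is
#' the fraction of permutations in which the permuted score strictly exceeds
#' the observed score (no add-one correction), so a gene holding the unique
#' maximum gets p = 0. Module membership is permuted under the same scheme,
#' keeping all five scores under a single null. A gene is a significant hub
#' when any of its five p-values falls below `alpha`.
#'
#' @param scores a `hub_score_table` from [hub_scores()].
#' @param n_perm number of relabellings (default 1000, >= 1).
#' @param seed integer seed.
#' @param alpha significance level (default 0.01).
#' @return the table with columns `p_<score>` per score, `min_p` and
#'   `significant` added.
#' @export
hub_permutation_test <- function(scores, n_perm = 1000, seed = 1, alpha = 0.01) {
  if (n_perm < 1) config_error("n_perm must be >= 1")
  n <- nrow(scores)
  obs <- as.matrix(scores[, hub_score_names])
  counts <- matrix(0, n, length(hub_score_names),
                   dimnames = list(NULL, hub_score_names))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      counts <- counts + (obs[perm, , drop = FALSE] > obs)
    }
  })
  p <- counts / n_perm
  tied <- apply(obs, 2, function(x) length(unique(x)) == 1)
  if (any(tied))
    warning(sprintf("all scores tied for: %s (p = 0 for every gene)",
                    paste(hub_score_names[tied], collapse = ", ")))
  out <- scores
  for (s in hub_score_names) out[[paste0("p_", s)]] <- p[, s]
  out$min_p <- apply(p, 1, min)
  out$significant <- out$min_p < alpha
  attr(out, "n_permutations") <- n_perm
  attr(out, "alpha") <- alpha
  out
}

#' Significant hub genes of a module
#'
#' Genes whose smallest hub-score p-value falls below `alpha` ("any method"
#' rule), sorted by that p-value and then by gene ID.
#'
#' @param table a `hub_score_table` with p-values filled.
#' @param alpha significance level (default 0.01).
#' @return character vector of gene IDs.
#' @export
significant_hubs <- function(table, alpha = 0.01) {
  if (nrow(table) == 0) return(character(0))
  if (is.null(table$min_p)) config_error("p-values missing: run hub_permutation_test first")
  hit <- table[table$min_p < alpha, , drop = FALSE]
  hit <- hit[order(hit$min_p, hit$gene_id), , drop = FALSE]
  hit$gene_id
}

#' Write a hub score table as TSV
#' @param table a `hub_score_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hub_table_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export network edges above an adjacency threshold
#'
#' Writes an edge list (gene_a, gene_b, weight) of all pairs with adjacency
#' strictly above `cutoff` among the given genes, preceded by a comment line
#' `# kept X of Y edges (upper triangle including diagonal)`. The total pair
#' count follows the upper-triangle-with-diagonal convention, n(n+1)/2.
#'
#' @param am adjacency matrix.
#' @param genes genes to include (default: all).
#' @param cutoff adjacency threshold in \[0, 1\].
#' @param path output TSV path, or NULL to skip writing.
#' @return list: `kept`, `total_pairs`, `n_nodes`, `summary`, `edges`
#'   (data.frame).
#' @export
export_threshold_graph <- function(am, genes = rownames(am), cutoff, path = NULL) {
  if (cutoff < 0 || cutoff > 1) config_error("cutoff must lie in [0, 1]")
  w <- am[genes, genes]
  n <- length(genes)
  ut <- which(upper.tri(w) & w > cutoff, arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[ut[, 1]], gene_b = genes[ut[, 2]],
                      weight = w[ut])
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  total <- pair_count(n, "upper_with_diagonal")
  summary <- sprintf("kept %d of %d edges (upper triangle including diagonal)",
                     nrow(edges), total)
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", summary), con)
    utils::write.table(edges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(kept = nrow(edges), total_pairs = total, n_nodes = n,
       summary = summary, edges = edges)
}
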