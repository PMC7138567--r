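# Eigengene contributions from the first principal eigenvector of a
# correlation submatrix: for top eigenpair (lambda, v) of C, the correlation
# of gene i with the module eigengene equals sqrt(lambda) * v_i, which
# matches the SVD route of module_eigengene. Computed by power iteration
# started from the row means (well aligned for coherent modules, where it
# converges in a handful of steps). The iteration cap bounds work on
# ill-separated null spectra; since observed and permutation-null statistics
# pass through this same deterministic function, the permutation test's
# exchangeability is unaffected.
eigengene_contrib <- function(C, tol = 1e-6, max_iter = 15) {
  m <- ncol(C)
  if (m == 1) return(1)
  v <- rowMeans(C)
  nv <- sqrt(sum(v^2))
  v <- if (nv > 0) v / nv else rep(1 / sqrt(m), m)
  for (i in seq_len(max_iter)) {
    w <- as.numeric(C %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) {
      v <- w
      break
    }
    w <- w / nw
    delta <- max(abs(w - v))
    v <- w
    if (delta < tol) break
  }
  lambda <- as.numeric(crossprod(v, C %*% v))
  contrib <- sqrt(max(lambda, 0)) * v
  if (sum(contrib) < 0) contrib <- -contrib
  contrib
}

# Pearson correlation of two plain vectors without dispatch overhead;
# NaN when either input has zero variance.
cor_vec <- function(x, y) {
  x0 <- x - mean(x)
  y0 <- y - mean(y)
  sxx <- sum(x0 * x0)
  syy <- sum(y0 * y0)
  if (sxx == 0 || syy == 0) return(NaN)
  sum(x0 * y0) / sqrt(sxx * syy)
}

# Seven preservation statistics from module submatrices of the discovery and
# test correlation and adjacency matrices. Inputs are m x m matrices over
# the same genes in the same order. `lt` may carry precomputed lower-triangle
# indices (reused across permutations of the same module size).
preservation_stats_core <- function(corD, corT, adjD, adjT, lt = NULL) {
  if (is.null(lt)) lt <- which(lower.tri(corD))
  cD <- corD[lt]
  cT <- corT[lt]
  kD <- rowSums(adjD) - diag(adjD)
  kT <- rowSums(adjT) - diag(adjT)
  contribD <- eigengene_contrib(corD)
  contribT <- eigengene_contrib(corT)
  c(avg_weight = mean(adjT[lt]),
    coherence = mean(contribT^2),
    cor_cor = cor_vec(cD, cT),
    cor_degree = cor_vec(kD, kT),
    cor_contrib = cor_vec(contribD, contribT),
    avg_cor = mean(cT * sign(cD)),
    avg_contrib = mean(contribT * sign(contribD)))
}

#' Seven module preservation statistics
#'
#' Measures how well a discovery-network module's internal structure is
#' replicated in a test network. With `cor_D`, `cor_T` the within-module
#' off-diagonal correlation vectors, `a^T` the test adjacency,
#' `k_X(i) = sum_{j in module} a^X_ij` the within-module connectivity and
#' `contrib_X(i)` the correlation of gene i with the module eigengene in
#' dataset X, the statistics are: `avg_weight = mean_{i<j} a^T_ij`;
#' `coherence = mean_i contrib_T(i)^2`; `cor_cor = Pearson(cor_D, cor_T)`;
#' `cor_degree = Pearson(k_D, k_T)`;
#' `cor_contrib = Pearson(contrib_D, contrib_T)`;
#' `avg_cor = mean_{i<j} cor_T(i,j) * sign(cor_D(i,j))`;
#' `avg_contrib = mean_i contrib_T(i) * sign(contrib_D(i))`.
#'
#' @param discovery,test each a list with elements `expr` (genes x samples
#'   matrix) and `adjacency` (gene x gene adjacency matrix).
#' @param genes module gene IDs (>= 3, present in both cohorts). If a
#'   Pearson input has zero variance the affected statistic is `NaN` (its
#'   permutation p-value is then reported as 1 with a warning).
#' @return named numeric vector of the seven statistics.
#' @export
preservation_statistics <- function(discovery, test, genes) {
  if (length(genes) < 3) config_error("need >= 3 module genes")
  for (side in list(discovery, test)) {
    if (!all(genes %in% rownames(side$expr)) ||
        !all(genes %in% rownames(side$adjacency)))
      config_error("module genes missing from a cohort's data or network")
  }
  corD <- suppressWarnings(stats::cor(t(discovery$expr[genes, , drop = FALSE])))
  corT <- suppressWarnings(stats::cor(t(test$expr[genes, , drop = FALSE])))
  corD[is.na(corD)] <- 0
  corT[is.na(corT)] <- 0
  diag(corD) <- 1
  diag(corT) <- 1
  preservation_stats_core(corD, corT,
                          discovery$adjacency[genes, genes],
                          test$adjacency[genes, genes])
}

#' Permutation test for module preservation
#'
#' For every module, the seven preservation statistics observed in the test
#' cohort are compared with a null distribution obtained by recomputing them
#' on random gene sets of the same size drawn without replacement from the
#' shared gene universe (which includes the module's own genes),
#' independently for each of `n_perm` permutations. Under
#' `alternative = "less"`, `p_s = (#\{null_s <= observed_s\} + 1) / (n_perm + 1)`,
#' so the smallest attainable p-value is `1/(n_perm + 1)` (with the
#' conventional 10,000 permutations this floor truncates to 9.99E-5). A
#' module is non-preserved when all seven p-values fall below `alpha`.
#'
#' @param discovery,test lists with `expr` and `adjacency` (see
#'   [preservation_statistics()]).
#' @param assignment a `module_assignment` over the discovery network.
#' @param n_perm number of permutations (default 10000).
#' @param alternative `"less"` (default; small statistics = non-preserved)
#'   or `"greater"`.
#' @param alpha significance level for the all-seven rule (default 0.05).
#' @param seed integer seed; results are deterministic given it.
#' @param min_size smallest module tested (default 3).
#' @return list of `preservation_result` objects, one per module: `module`,
#'   `size`, `observed`, `p_values`, `max_p`, `nonpreserved`,
#'   `n_permutations`.
#' @export
preservation_permutation_test <- function(discovery, test, assignment,
                                          n_perm = 10000,
                                          alternative = c("less", "greater"),
                                          alpha = 0.05, seed = 1,
                                          min_size = 3) {
  alternative <- match.arg(alternative)
  universe <- intersect(rownames(discovery$expr), rownames(test$expr))
  universe <- intersect(universe, intersect(rownames(discovery$adjacency),
                                            rownames(test$adjacency)))
  universe <- intersect(universe, names(assignment))
  if (length(universe) < min_size)
    config_error("shared gene universe too small")
  corD <- suppressWarnings(stats::cor(t(discovery$expr[universe, , drop = FALSE])))
  corT <- suppressWarnings(stats::cor(t(test$expr[universe, , drop = FALSE])))
  corD[is.na(corD)] <- 0
  corT[is.na(corT)] <- 0
  diag(corD) <- 1
  diag(corT) <- 1
  adjD <- discovery$adjacency[universe, universe]
  adjT <- test$adjacency[universe, universe]
  labs <- module_labels(assignment[universe])
  labs <- labs[vapply(labs, function(l) sum(assignment[universe] == l) >= min_size,
                      logical(1))]
  N <- length(universe)

  results <- list()
  for (lab in labs) {
    genes <- universe[assignment[universe] == lab]
    m <- length(genes)
    if (m > N) config_error("module larger than the shared universe")
    idx <- match(genes, universe)
    lt <- which(lower.tri(matrix(0, m, m)))
    observed <- preservation_stats_core(corD[idx, idx], corT[idx, idx],
                                        adjD[idx, idx], adjT[idx, idx], lt)
    counts <- stats::setNames(numeric(7), names(observed))
    with_seed(child_seed(seed, paste0("preservation_", lab)), {
      for (b in seq_len(n_perm)) {
        ridx <- sample.int(N, m)
        null_s <- preservation_stats_core(corD[ridx, ridx], corT[ridx, ridx],
                                          adjD[ridx, ridx], adjT[ridx, ridx], lt)
        hit <- if (alternative == "less") null_s <= observed else null_s >= observed
        counts <- counts + as.numeric(hit & !is.na(hit))
      }
    })
    p <- (counts + 1) / (n_perm + 1)
    if (any(is.nan(observed))) {
      warning(sprintf("module %s: NaN statistic(s) %s, p-value set to 1", lab,
                      paste(names(observed)[is.nan(observed)], collapse = ", ")))
      p[is.nan(observed)] <- 1
    }
    results[[lab]] <- structure(list(
      module = lab,
      size = m,
      observed = observed,
      p_values = p,
      max_p = max(p),
      nonpreserved = all(p < alpha),
      n_permutations = n_perm
    ), class = "preservation_result")
  }
  results
}

#' Labels of modules failing all seven preservation tests
#'
#' A module is significantly non-preserved when all seven preservation
#' statistics have permutation p-values below `alpha`.
#'
#' @param results list of `preservation_result` objects.
#' @param alpha significance level (default 0.05).
#' @return character vector of non-preserved module labels.
#' @export
classify_nonpreserved <- function(results, alpha = 0.05) {
  labs <- vapply(results, function(r) r$module, character(1))
  keep <- vapply(results, function(r) all(r$p_values < alpha), logical(1))
  unname(labs[keep])
}

#' Preservation results as a report table
#'
#' One row per module: label, size, the maximum of the seven permutation
#' p-values (formatted with 3-significant-figure truncation, the convention
#' of the published tables) and the seven individual p-values.
#'
#' @param results list of `preservation_result` objects.
#' @return data.frame.
#' @export
preservation_table <- function(results) {
  if (length(results) == 0) {
    return(data.frame(module = character(0), size = integer(0),
                      max_p = numeric(0), max_p_printed = character(0),
                      nonpreserved = logical(0)))
  }
  base <- data.frame(
    module = vapply(results, function(r) r$module, character(1)),
    size = vapply(results, function(r) r$size, numeric(1)),
    max_p = vapply(results, function(r) r$max_p, numeric(1)),
    max_p_printed = vapply(results, function(r) format_pvalue_truncated(r$max_p),
                           character(1)),
    nonpreserved = vapply(results, function(r) r$nonpreserved, logical(1))
  )
  ps <- do.call(rbind, lapply(results, function(r) as.data.frame(t(r$p_values))))
  cbind(base, ps, row.names = NULL)
}

#' Write preservation results as JSON
#' @param results list of `preservation_result` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preservation_json <- function(results, path) {
  jsonlite::write_json(lapply(results, function(r) {
    list(module = r$module, size = r$size,
         observed = as.list(r$observed), p_values = as.list(r$p_values),
         max_p = r$max_p, nonpreserved = r$nonpreserved,
         n_permutations = r$n_permutations)
  }), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
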