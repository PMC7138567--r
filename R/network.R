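#' Pairwise Pearson correlation matrix over genes
#'
#' @param expr genes x samples numeric matrix (>= 3 samples, no missing
#'   values). Genes with zero variance receive correlation 0 to every other
#'   gene (recorded in attribute `zero_variance` with a warning); the
#'   diagonal is forced to 1.
#' @return symmetric gene x gene correlation matrix.
#' @export
correlation_matrix <- function(expr) {
  if (ncol(expr) < 3) config_error("need >= 3 samples to correlate")
  if (anyNA(expr)) {
    bad <- rownames(expr)[apply(is.na(expr), 1, any)]
    config_error("missing values in gene(s): %s",
                 paste(utils::head(bad, 5), collapse = ", "))
  }
  sds <- apply(expr, 1, stats::sd)
  zero_var <- rownames(expr)[sds == 0]
  cm <- suppressWarnings(stats::cor(t(expr)))
  if (length(zero_var) > 0) {
    warning(sprintf("%d zero-variance gene(s) set to correlation 0: %s",
                    length(zero_var),
                    paste(utils::head(zero_var, 5), collapse = ", ")))
    cm[zero_var, ] <- 0
    cm[, zero_var] <- 0
  }
  diag(cm) <- 1
  attr(cm, "zero_variance") <- zero_var
  cm
}

#' Soft-thresholded adjacency from a correlation matrix
#'
#' Unsigned: `a_ij = |r_ij|^power`; signed: `a_ij = ((1 + r_ij)/2)^power`.
#' The diagonal is set to 1.
#'
#' @param cm correlation matrix (symmetric, unit diagonal).
#' @param power positive integer soft-thresholding exponent.
#' @param network_type `"unsigned"` (default) or `"signed"`.
#' @return adjacency matrix in \[0, 1\] with attributes `power` and
#'   `network_type`.
#' @export
adjacency <- function(cm, power, network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  if (power < 1) config_error("power must be >= 1")
  check_square_named(cm, "correlation matrix")
  am <- if (network_type == "unsigned") abs(cm)^power else ((1 + cm) / 2)^power
  diag(am) <- 1
  attr(am, "power") <- power
  attr(am, "network_type") <- network_type
  attr(am, "zero_variance") <- NULL
  am
}

#' Scale-free topology fit of a connectivity vector
#'
#' Connectivity is binned into `n_bins` equal-width bins (empty bins
#' dropped); `log10(frequency)` is regressed on `log10(mean k)` over the
#' occupied bins and the fit is `-sign(slope) * R^2`, so a decaying
#' (scale-free-like) connectivity distribution scores positively. Degenerate
#' inputs (constant connectivity, a single occupied bin) return 0 with a
#' warning.
#'
#' @param k numeric vector of node connectivities.
#' @param n_bins number of equal-width bins (default 10).
#' @return signed R-squared in \[-1, 1\].
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (diff(range(k)) == 0) {
    warning("constant connectivity: scale-free fit undefined, returning 0")
    return(0)
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  keep <- counts > 0
  if (sum(keep) < 2) {
    warning("fewer than 2 occupied connectivity bins: returning 0")
    return(0)
  }
  mean_k <- vapply(levels(bin)[keep], function(l) mean(k[bin == l]), numeric(1))
  frac <- counts[keep] / length(k)
  x <- log10(mean_k)
  y <- log10(frac)
  if (stats::sd(x) == 0) {
    warning("degenerate connectivity bins: returning 0")
    return(0)
  }
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  -sign(slope) * r2
}

#' Scan soft-thresholding powers for scale-free topology fit
#'
#' For each power the adjacency is formed, connectivity
#' `k_i = sum_{j != i} a_ij` computed, k binned into `n_bins` equal-width
#' bins (empty bins dropped), and `log10(frequency)` regressed on
#' `log10(mean k)`. The signed fit is `-sign(slope) * R^2`. The chosen power
#' is the smallest one whose signed fit reaches `r2_target`.
#'
#' @param cm correlation matrix.
#' @param powers integer powers to scan (default 1:20).
#' @param n_bins connectivity bins (default 10).
#' @param network_type `"unsigned"` or `"signed"`.
#' @param r2_target scale-free fit target (default 0.85).
#' @return list of class `soft_threshold_report`: `fit` (data.frame with
#'   `power`, `signed_r2`, `mean_connectivity`), `chosen_power` (integer or
#'   NA), `r2_target`, `network_type`.
#' @export
soft_threshold_scan <- function(cm, powers = 1:20, n_bins = 10,
                                network_type = c("unsigned", "signed"),
                                r2_target = 0.85) {
  network_type <- match.arg(network_type)
  if (length(powers) == 0) config_error("powers must be non-empty")
  if (nrow(cm) < n_bins) config_error("need at least n_bins genes")
  rows <- lapply(powers, function(p) {
    am <- adjacency(cm, p, network_type)
    k <- rowSums(am) - diag(am)
    data.frame(power = p,
               signed_r2 = scale_free_fit(k, n_bins),
               mean_connectivity = mean(k))
  })
  fit <- do.call(rbind, rows)
  ok <- fit$power[fit$signed_r2 >= r2_target]
  chosen <- if (length(ok) > 0) min(ok) else NA_integer_
  structure(list(fit = fit, chosen_power = chosen, r2_target = r2_target,
                 network_type = network_type),
            class = "soft_threshold_report")
}

#' @export
print.soft_threshold_report <- function(x, ...) {
  cat(sprintf("Soft-threshold scan (%s network, target signed R^2 = %.2f)\n",
              x$network_type, x$r2_target))
  print(x$fit, row.names = FALSE)
  if (is.na(x$chosen_power)) {
    cat("No power reached the target.\n")
  } else {
    cat(sprintf("Chosen power: %d\n", x$chosen_power))
  }
  invisible(x)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for i != j, where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{j != i} a_ij`; the
#' diagonal is 1. The adjacency diagonal participates in neither k nor l.
#' Computed with one matrix product; equals the naive triple-loop definition
#' to numerical precision.
#'
#' @param am adjacency matrix in \[0, 1\] with unit diagonal.
#' @return TOM matrix in \[0, 1\], unit diagonal, same dimnames.
#' @export
topological_overlap <- function(am) {
  check_square_named(am, "adjacency matrix")
  a <- am
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  if (any(denom <= 0)) stop("internal error: non-positive TOM denominator")
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(am)
  tom
}

#' Write a named square matrix as TSV with gene headers
#' @param m matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
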