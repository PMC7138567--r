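#' Average-linkage dendrogram of topological overlap dissimilarity
#'
#' Clusters genes on dissimilarity `1 - TOM` with average linkage. `hclust`
#' resolves ties deterministically (equal-height merges proceed by smallest
#' indices), so repeated runs on the same input give identical trees.
#'
#' @param tom TOM (or any similarity) matrix in \[0, 1\] with unit diagonal.
#' @return an `hclust` object with gene labels.
#' @export
hierarchical_tree <- function(tom) {
  check_square_named(tom, "TOM matrix")
  if (nrow(tom) < 2) config_error("need >= 2 genes to cluster")
  stats::hclust(stats::as.dist(1 - tom), method = "average")
}

# Leaf sets for every internal node of an hclust merge matrix.
node_leaves <- function(merge) {
  n_nodes <- nrow(merge)
  out <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    grab <- function(x) if (x < 0) -x else out[[x]]
    out[[i]] <- c(grab(merge[i, 1]), grab(merge[i, 2]))
  }
  out
}

#' Dynamic hybrid tree cut
#'
#' Two-stage module identification on a dendrogram of `1 - TOM`
#' dissimilarity, in the spirit of the dynamic hybrid cut. Stage 1 extracts
#' candidate branches top-down: merges at or above the cut ceiling (99% of
#' the dendrogram height range) are always broken, and a branch strictly
#' below the ceiling is further split into its two children when both would
#' hold at least `min_module_size` genes and both hang below the merge by a
#' height gap of at least `(0.25 - 0.05 * deep_split)` times the height
#' range — so a higher `deep_split` resolves more, smaller clusters.
#' Branches below `min_module_size` dissolve. Stage 2 assigns every
#' dissolved or unassigned gene to the cluster with the smallest average
#' dissimilarity, provided the gene's average topological-overlap similarity
#' to that cluster exceeds one tenth of the cluster's loosest member's
#' within-cluster similarity (a multiplicative criterion, so it is invariant
#' to the scale compression high soft powers impose on the overlap);
#' otherwise the gene stays `"unassigned"`.
#'
#' @param dend `hclust` tree from [hierarchical_tree()].
#' @param tom the TOM matrix the tree was built from.
#' @param deep_split split sensitivity, integer 0..4 (default 3).
#' @param min_module_size smallest reportable module (default 10, >= 2).
#' @return a named character vector gene -> module label (`"M1"`, `"M2"`, ...
#'   by decreasing size) with `"unassigned"` for background genes; attribute
#'   `provenance = "initial"`. Class `module_assignment`.
#' @export
dynamic_hybrid_cut <- function(dend, tom, deep_split = 3, min_module_size = 10) {
  if (min_module_size < 2) config_error("min_module_size must be >= 2")
  if (!deep_split %in% 0:4) config_error("deep_split must be an integer in 0..4")
  genes <- dend$labels
  n <- length(genes)
  diss <- 1 - tom[genes, genes]
  h <- dend$height
  merge <- dend$merge
  max_h <- max(h)
  min_h <- min(h)
  rng <- max_h - min_h
  gap_min <- (0.25 - 0.05 * deep_split) * rng
  cut_height <- min_h + 0.99 * rng
  # tolerance so numerically flat trees (all merges at one height) behave as
  # structureless rather than as one giant branch
  eps <- 1e-9 * max(1, abs(max_h))
  leaves <- node_leaves(merge)
  top_of <- function(x) if (x < 0) 0 else h[x]
  size_of <- function(x) if (x < 0) 1L else length(leaves[[x]])

  clusters <- list()
  stack <- nrow(merge) # root node index
  while (length(stack) > 0) {
    node <- stack[[1]]
    stack <- stack[-1]
    hn <- h[node]
    kids <- merge[node, ]
    gaps <- hn - vapply(kids, top_of, numeric(1))
    sizes <- vapply(kids, size_of, integer(1))
    split <- hn >= cut_height - eps ||
      (min(gaps) >= gap_min && all(sizes >= min_module_size))
    if (split) {
      for (kid in kids) {
        if (kid > 0) stack <- c(stack, kid)
        # leaf children dissolve into stage 2
      }
    } else {
      clusters[[length(clusters) + 1]] <- list(idx = leaves[[node]], top = hn)
    }
  }

  accepted <- Filter(function(cl) {
    length(cl$idx) >= min_module_size && cl$top < cut_height - eps
  }, clusters)

  assignment <- rep("unassigned", n)
  names(assignment) <- genes
  if (length(accepted) > 0) {
    # label by decreasing size
    ord <- order(-vapply(accepted, function(cl) length(cl$idx), numeric(1)))
    accepted <- accepted[ord]
    for (m in seq_along(accepted)) {
      assignment[accepted[[m]]$idx] <- sprintf("M%d", m)
    }
    # stage 2: PAM-like assignment of leftover genes
    labs <- sprintf("M%d", seq_along(accepted))
    member_idx <- lapply(accepted, `[[`, "idx")
    sim <- 1 - diss
    thr <- vapply(member_idx, function(ii) {
      min(vapply(ii, function(i) mean(sim[i, setdiff(ii, i)]), numeric(1))) / 10
    }, numeric(1))
    free <- which(assignment == "unassigned")
    for (i in free) {
      s_m <- vapply(member_idx, function(ii) mean(sim[i, ii]), numeric(1))
      best <- which.max(s_m)
      if (s_m[best] > thr[best] && s_m[best] > 0) assignment[i] <- labs[best]
    }
  }
  structure(assignment, provenance = "initial", class = "module_assignment")
}

# Unique module labels of an assignment, unassigned excluded, by size.
module_labels <- function(assign) {
  tab <- table(assign[assign != "unassigned"])
  if (length(tab) == 0) return(character(0))
  names(sort(tab, decreasing = TRUE))
}

#' Module eigengene (first principal component over samples)
#'
#' Genes are z-scored across samples; the eigengene is the first right
#' singular vector of the z-scored genes x samples matrix (unit norm), with
#' sign flipped so its correlation with the module's mean z-scored profile
#' is non-negative. `variance_explained` is the first squared singular value
#' over the total.
#'
#' @param expr genes x samples matrix.
#' @param genes genes forming the module (>= 2; >= 3 samples required).
#'   Zero-variance genes are dropped with a warning.
#' @return list of class `eigengene`: `values` (named by sample),
#'   `variance_explained`, `genes`.
#' @export
module_eigengene <- function(expr, genes) {
  if (length(genes) < 2) config_error("a module eigengene needs >= 2 genes")
  if (ncol(expr) < 3) config_error("need >= 3 samples")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0)
    config_error("genes absent from expression matrix: %s",
                 paste(utils::head(missing, 5), collapse = ", "))
  x <- expr[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance gene(s) from eigengene",
                    sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) == 0) config_error("all module genes have zero variance")
  }
  z <- t(scale(t(x)))
  sv <- svd(z)
  e <- sv$v[, 1]
  ve <- sv$d[1]^2 / sum(sv$d^2)
  mean_profile <- colMeans(z)
  ref <- if (stats::sd(mean_profile) > 0) {
    stats::cor(e, mean_profile)
  } else {
    stats::cor(e, z[1, ])
  }
  if (!is.na(ref) && ref < 0) e <- -e
  structure(list(values = stats::setNames(e, colnames(expr)),
                 variance_explained = ve,
                 genes = rownames(x)),
            class = "eigengene")
}

# Eigengene matrix (samples x modules) for all modules of an assignment.
module_eigengenes <- function(expr, assign) {
  labs <- module_labels(assign)
  me <- vapply(labs, function(l) {
    gs <- names(assign)[assign == l]
    if (length(gs) >= 2) {
      module_eigengene(expr, gs)$values
    } else {
      z <- as.numeric(scale(expr[gs, ]))
      z / sqrt(sum(z^2))
    }
  }, numeric(ncol(expr)))
  rownames(me) <- colnames(expr)
  me
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively computes eigengenes, clusters them on `1 - correlation`
#' (average linkage), merges every group of modules joined strictly below
#' `cut_height` (i.e. eigengene correlation above `1 - cut_height`), and
#' repeats until no merge occurs. A merged module takes the label of its
#' largest constituent. Terminates because the module count strictly
#' decreases with every merge round.
#'
#' @param assign a `module_assignment`.
#' @param expr genes x samples matrix.
#' @param cut_height merge threshold on eigengene dissimilarity
#'   (default 0.05).
#' @return the merged `module_assignment` (provenance `"merged"`).
#' @export
merge_close_modules <- function(assign, expr, cut_height = 0.05) {
  if (length(module_labels(assign)) == 0) config_error("no modules to merge")
  out <- assign
  repeat {
    labs <- module_labels(out)
    if (length(labs) < 2) break
    me <- module_eigengenes(expr, out)
    d <- 1 - stats::cor(me)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    groups <- stats::cutree(hc, h = cut_height - 1e-12)
    if (max(groups) == length(labs)) break
    sizes <- table(factor(out, levels = labs))
    for (g in unique(groups)) {
      members <- colnames(me)[groups == g]
      if (length(members) < 2) next
      target <- members[which.max(sizes[members])]
      out[out %in% members] <- target
    }
  }
  structure(unclass(out), provenance = "merged", class = "module_assignment")
}

#' k-means refinement of module assignments
#'
#' Reduces misplaced genes after hierarchical detection: with k equal to the
#' number of modules and centroids initialized to the module eigengenes,
#' each iteration reassigns every assigned gene to the centroid with the
#' smallest distance `1 - cor(gene profile, eigengene)` and recomputes the
#' eigengenes. Unassigned genes do not participate. Iteration stops when no
#' gene moves, when `max_iter` is reached, or when an update would increase
#' the total `1 - correlation` objective (the offending update is reverted,
#' which guarantees the objective is non-increasing across accepted
#' iterations). Modules emptied by reassignment are dropped with a warning.
#'
#' @param assign a `module_assignment`.
#' @param expr genes x samples matrix.
#' @param max_iter maximum iterations (default 30); 0 returns the input
#'   assignment with updated provenance.
#' @return refined `module_assignment` (provenance `"kmeans_refined"`), with
#'   attribute `objective_trace` recording the objective per iteration.
#' @export
kmeans_refine <- function(assign, expr, max_iter = 30) {
  labs <- module_labels(assign)
  if (length(labs) == 0) config_error("no modules to refine")
  out <- unclass(assign)
  trace <- numeric(0)
  if (max_iter > 0) {
    assigned <- names(out)[out != "unassigned"]
    z <- t(scale(t(expr[assigned, , drop = FALSE])))
    ok <- apply(z, 1, function(r) all(is.finite(r)))
    z <- z[ok, , drop = FALSE]
    assigned <- rownames(z)
    objective <- function(labels, me) {
      d <- 1 - stats::cor(t(z), me)
      sum(d[cbind(seq_along(assigned), match(labels[assigned], colnames(me)))])
    }
    prev_obj <- Inf
    for (it in seq_len(max_iter)) {
      labs <- module_labels(out)
      if (length(labs) == 0) break
      me <- module_eigengenes(expr, out)
      d <- 1 - stats::cor(t(z), me) # genes x modules
      cur_col <- match(out[assigned], colnames(me))
      new_col <- max.col(-d, ties.method = "first")
      # stay in the current module when tied with the minimum
      stay <- d[cbind(seq_along(assigned), cur_col)] <=
        d[cbind(seq_along(assigned), new_col)] + 1e-12
      new_col[stay] <- cur_col[stay]
      proposed <- out
      proposed[assigned] <- colnames(me)[new_col]
      kept <- module_labels(proposed)
      if (length(kept) < length(labs)) {
        warning(sprintf("module(s) emptied during k-means refinement: %s",
                        paste(setdiff(labs, kept), collapse = ", ")))
      }
      me_new <- module_eigengenes(expr, proposed)
      obj <- objective(proposed, me_new)
      if (obj > prev_obj + 1e-10) break # revert: objective must not increase
      trace <- c(trace, obj)
      moved <- any(proposed[assigned] != out[assigned])
      out <- proposed
      prev_obj <- obj
      if (!moved) break
    }
  }
  structure(out, provenance = "kmeans_refined", objective_trace = trace,
            class = "module_assignment")
}

#' Map module labels to presentation color names
#'
#' Module labels are stable strings ("M1", "M2", ... by decreasing size);
#' this utility maps them onto the conventional color-name palette used in
#' co-expression reports. `"unassigned"` maps to `"grey"`.
#'
#' @param labels character vector of module labels.
#' @return named character vector of color names.
#' @export
module_color_mapping <- function(labels) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
               "lightgreen", "lightyellow", "royalblue", "darkred",
               "darkgreen", "darkturquoise", "darkgrey", "orange",
               "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
               "paleturquoise", "violet", "darkolivegreen", "darkmagenta",
               "sienna3", "yellowgreen", "skyblue3", "plum1", "orangered4",
               "mediumpurple3", "lightsteelblue1", "lightcyan1", "ivory",
               "floralwhite", "darkorange2", "brown4", "bisque4",
               "darkslateblue", "plum2", "thistle2")
  uniq <- setdiff(unique(labels), "unassigned")
  uniq <- uniq[order(suppressWarnings(as.integer(sub("^M", "", uniq))), uniq)]
  cols <- rep_len(palette, length(uniq))
  map <- stats::setNames(cols, uniq)
  out <- stats::setNames(
    ifelse(labels == "unassigned", "grey", map[labels]), labels)
  out
}

#' Write a module assignment as TSV (`gene_id`, `module`)
#' @param assign a `module_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_module_assignment_tsv <- function(assign, path) {
  utils::write.table(
    data.frame(gene_id = names(assign), module = as.character(assign)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
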