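# Two-factor expression fixture with explicit gene->factor design, for
# merge/refinement contracts.
two_factor_expr <- function(n_per = 12, n_samples = 500, noise = 0.3, seed = 5) {
  set.seed(seed)
  u1 <- rnorm(n_samples)
  u2 <- rnorm(n_samples)
  genes <- sprintf("g%02d", seq_len(2 * n_per))
  expr <- matrix(rnorm(2 * n_per * n_samples, sd = noise), 2 * n_per,
                 n_samples, dimnames = list(genes, sprintf("s%03d", 1:n_samples)))
  w <- runif(2 * n_per, 0.6, 0.9)
  expr[1:n_per, ] <- expr[1:n_per, ] + outer(w[1:n_per], u1)
  expr[(n_per + 1):(2 * n_per), ] <- expr[(n_per + 1):(2 * n_per), ] +
    outer(w[(n_per + 1):(2 * n_per)], u2)
  list(expr = expr, factor_of = rep(c("F1", "F2"), each = n_per))
}

test_that("average-linkage trees merge identical genes first and are deterministic", {
  sim <- diag(1, 4)
  sim[1, 2] <- sim[2, 1] <- 1      # identical pair: dissimilarity 0
  sim[3, 4] <- sim[4, 3] <- 0.6
  dimnames(sim) <- list(sprintf("g%d", 1:4), sprintf("g%d", 1:4))
  hc <- hierarchical_tree(sim)
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$merge[1, ], c(-1, -2))

  # two tight pairs merge before the cross-merge, at hand-computable heights
  d <- matrix(0.9, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.2
  diag(d) <- 0
  sim2 <- 1 - d
  dimnames(sim2) <- dimnames(sim)
  hc2 <- hierarchical_tree(sim2)
  expect_equal(sort(hc2$height), c(0.1, 0.2, 0.9), tolerance = 1e-12)
  expect_setequal(hc2$merge[1, ], c(-1, -2))
  expect_setequal(hc2$merge[2, ], c(-3, -4))

  # equidistant triple: deterministic merge order, repeated runs identical
  eq <- matrix(0.5, 3, 3)
  diag(eq) <- 1
  dimnames(eq) <- list(sprintf("g%d", 1:3), sprintf("g%d", 1:3))
  t1 <- hierarchical_tree(eq)
  t2 <- hierarchical_tree(eq)
  expect_identical(t1$merge, t2$merge)
  expect_setequal(t1$merge[1, ], c(-1, -2))
})

test_that("dynamic hybrid cut recovers planted blocks exactly at high signal", {
  sim <- make_block_similarity(c(30, 30, 30), within = 0.8, between = 0.05)
  hc <- hierarchical_tree(sim)
  assign <- dynamic_hybrid_cut(hc, sim, deep_split = 3, min_module_size = 10)
  labs <- setdiff(unique(assign), "unassigned")
  expect_length(labs, 3)
  expect_equal(adjusted_rand_index(attr(sim, "blocks"), unclass(assign)), 1.0)
  expect_identical(attr(assign, "provenance"), "initial")
})

test_that("a structureless dissimilarity leaves every gene unassigned", {
  n <- 40
  sim <- matrix(0.3, n, n, dimnames = list(sprintf("g%02d", 1:n),
                                           sprintf("g%02d", 1:n)))
  diag(sim) <- 1
  hc <- hierarchical_tree(sim)
  assign <- dynamic_hybrid_cut(hc, sim)
  expect_true(all(assign == "unassigned"))
})

test_that("blocks below min_module_size are never reported as modules", {
  sim <- make_block_similarity(c(30, 5), within = 0.8, between = 0.05)
  hc <- hierarchical_tree(sim)
  assign <- dynamic_hybrid_cut(hc, sim, min_module_size = 10)
  blocks <- attr(sim, "blocks")
  small <- names(blocks)[blocks == "B2"]
  big <- names(blocks)[blocks == "B1"]
  # the big block forms one module; the 5-gene block is not its own module
  expect_length(setdiff(unique(assign[big]), "unassigned"), 1)
  expect_false(any(table(assign[small]) == 5 &
                     !names(table(assign[small])) %in%
                       c(unique(assign[big]), "unassigned")))
  expect_error(dynamic_hybrid_cut(hc, sim, min_module_size = 1), "min_module_size")
  expect_error(dynamic_hybrid_cut(hc, sim, deep_split = 5), "deep_split")
})

test_that("module eigengene is the oriented first PC with correct variance share", {
  set.seed(11)
  base <- rnorm(50)
  expr <- rbind(
    a = 2 * base + 3,
    b = -1 * base + 5,
    c = 0.5 * base - 1
  )
  colnames(expr) <- sprintf("s%02d", 1:50)
  eig <- module_eigengene(expr, c("a", "b", "c"))
  expect_equal(eig$variance_explained, 1, tolerance = 1e-12)
  z <- as.numeric(scale(base))
  z <- z / sqrt(sum(z^2))
  expect_equal(abs(stats::cor(eig$values, z)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(eig$values^2)), 1, tolerance = 1e-12)

  # two genes, one the negation of the other: rank-1 with +1/-1 correlations
  expr2 <- rbind(a = base, b = -base)
  colnames(expr2) <- colnames(expr)
  eig2 <- module_eigengene(expr2, c("a", "b"))
  expect_equal(eig2$variance_explained, 1, tolerance = 1e-12)
  cors <- stats::cor(t(expr2), eig2$values)
  expect_equal(sort(as.numeric(cors)), c(-1, 1), tolerance = 1e-12)
})

test_that("eigengene orientation and degeneracy contracts hold", {
  set.seed(12)
  for (i in 1:10) {
    expr <- matrix(rnorm(8 * 30), 8, 30,
                   dimnames = list(letters[1:8], sprintf("s%02d", 1:30)))
    eig <- module_eigengene(expr, letters[1:8])
    z <- t(scale(t(expr)))
    expect_gte(stats::cor(eig$values, colMeans(z)), 0)
  }
  expr <- rbind(a = rnorm(20), b = rep(1, 20), c = rnorm(20))
  colnames(expr) <- sprintf("s%02d", 1:20)
  expect_warning(eig <- module_eigengene(expr, c("a", "b", "c")), "zero-variance")
  expect_setequal(eig$genes, c("a", "c"))
  flat <- rbind(a = rep(1, 10), b = rep(2, 10))
  colnames(flat) <- sprintf("s%02d", 1:10)
  expect_error(suppressWarnings(module_eigengene(flat, c("a", "b"))),
               "zero variance")
  expect_error(module_eigengene(expr, "a"), ">= 2 genes")
})

test_that("modules sharing a latent factor merge; independent ones do not", {
  fx <- two_factor_expr()
  genes <- rownames(fx$expr)
  # split factor F1's genes into two artificial modules, F2 in a third
  assign <- structure(
    stats::setNames(c(rep("M1", 6), rep("M2", 6), rep("M3", 12)), genes),
    class = "module_assignment")
  merged <- merge_close_modules(assign, fx$expr, cut_height = 0.05)
  f1_labels <- unique(merged[fx$factor_of == "F1"])
  f2_labels <- unique(merged[fx$factor_of == "F2"])
  # M1 and M2 (same factor) merge into one label; M3 (independent) stays
  expect_length(f1_labels, 1)
  expect_true(f1_labels %in% c("M1", "M2"))
  expect_identical(f2_labels, "M3")
  expect_false(f1_labels %in% f2_labels)
  expect_length(unique(merged), 2)
  expect_identical(attr(merged, "provenance"), "merged")

  # single module: identity
  one <- structure(stats::setNames(rep("M1", 24), genes),
                   class = "module_assignment")
  expect_equal(as.character(merge_close_modules(one, fx$expr)),
               rep("M1", 24))
})

test_that("k-means refinement fixes a planted misplacement and is monotone", {
  fx <- two_factor_expr()
  genes <- rownames(fx$expr)
  correct <- stats::setNames(ifelse(fx$factor_of == "F1", "M1", "M2"), genes)
  # move one F2 gene into M1
  wrong <- correct
  moved <- names(wrong)[fx$factor_of == "F2"][1]
  wrong[moved] <- "M1"
  refined <- kmeans_refine(structure(wrong, class = "module_assignment"),
                           fx$expr)
  expect_identical(unname(refined[moved]), "M2")
  expect_equal(as.character(refined), unname(correct))
  trace <- attr(refined, "objective_trace")
  expect_true(all(diff(trace) <= 1e-10))
  expect_identical(attr(refined, "provenance"), "kmeans_refined")

  # fixed point: a correct assignment is returned unchanged
  fixed <- kmeans_refine(structure(correct, class = "module_assignment"),
                         fx$expr)
  expect_equal(as.character(fixed), unname(correct))

  # max_iter = 0: identity with provenance updated
  id0 <- kmeans_refine(structure(wrong, class = "module_assignment"),
                       fx$expr, max_iter = 0)
  expect_equal(as.character(id0), unname(wrong))
  expect_identical(attr(id0, "provenance"), "kmeans_refined")
})

test_that("module labels map to presentation colors with grey for unassigned", {
  map <- module_color_mapping(c("M1", "M2", "unassigned", "M1"))
  expect_identical(unname(map[3]), "grey")
  expect_identical(unname(map[1]), unname(map[4]))
  expect_false(map[1] == map[2])
})

test_that("end-to-end module recovery on a planted cohort is accurate", {
  cfg <- tiny_config(seed = 21)
  pair <- generate_cohort_pair(cfg)
  cm <- correlation_matrix(pair$cohort_a)
  scan <- soft_threshold_scan(cm)
  p <- if (is.na(scan$chosen_power)) {
    scan$fit$power[which.max(scan$fit$signed_r2)]
  } else scan$chosen_power
  tom <- topological_overlap(adjacency(cm, p))
  assign <- dynamic_hybrid_cut(hierarchical_tree(tom), tom)
  assign <- merge_close_modules(assign, pair$cohort_a)
  assign <- kmeans_refine(assign, pair$cohort_a)
  truth <- pair$truth$true_assignment
  expect_gte(adjusted_rand_index(truth, unclass(assign)[names(truth)]), 0.9)
})
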