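# Slow, independent implementation of the seven statistics: correlations via
# stats::cor, eigengene contributions via the SVD route of module_eigengene,
# explicit loops for the signed means.
preservation_stats_oracle <- function(discovery, test, genes) {
  eD <- module_eigengene(discovery$expr, genes)
  eT <- module_eigengene(test$expr, genes)
  contribD <- as.numeric(stats::cor(t(discovery$expr[genes, ]), eD$values))
  contribT <- as.numeric(stats::cor(t(test$expr[genes, ]), eT$values))
  if (sum(contribD) < 0) contribD <- -contribD
  if (sum(contribT) < 0) contribT <- -contribT
  corD <- stats::cor(t(discovery$expr[genes, ]))
  corT <- stats::cor(t(test$expr[genes, ]))
  aD <- discovery$adjacency[genes, genes]
  aT <- test$adjacency[genes, genes]
  m <- length(genes)
  sw <- 0; sc <- 0; np <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      sw <- sw + aT[i, j]
      sc <- sc + corT[i, j] * sign(corD[i, j])
      np <- np + 1
    }
  }
  kD <- rowSums(aD) - diag(aD)
  kT <- rowSums(aT) - diag(aT)
  lt <- lower.tri(corD)
  c(avg_weight = sw / np,
    coherence = mean(contribT^2),
    cor_cor = stats::cor(corD[lt], corT[lt]),
    cor_degree = stats::cor(kD, kT),
    cor_contrib = stats::cor(contribD, contribT),
    avg_cor = sc / np,
    avg_contrib = mean(contribT * sign(contribD)))
}

cohort_nets <- function(pair, power = 6) {
  list(
    d = list(expr = pair$cohort_a,
             adjacency = adjacency(correlation_matrix(pair$cohort_a), power)),
    t = list(expr = pair$cohort_b,
             adjacency = adjacency(correlation_matrix(pair$cohort_b), power))
  )
}

test_that("statistics are exact on the identity case and constant adjacency", {
  pair <- generate_cohort_pair(tiny_config(seed = 31))
  net <- cohort_nets(pair)
  genes <- names(pair$truth$true_assignment)[
    pair$truth$true_assignment == "M2"]
  s <- preservation_statistics(net$d, net$d, genes)
  expect_equal(unname(s["cor_cor"]), 1, tolerance = 1e-12)
  expect_equal(unname(s["cor_degree"]), 1, tolerance = 1e-12)
  expect_equal(unname(s["cor_contrib"]), 1, tolerance = 1e-9)
  expect_gt(unname(s["avg_cor"]), 0)
  expect_true(all(s[c("avg_weight", "coherence")] >= 0 &
                    s[c("avg_weight", "coherence")] <= 1))

  # uniform test adjacency: avg_weight equals the constant
  flat <- net$d
  flat$adjacency <- matrix(0.3, nrow(net$d$adjacency), ncol(net$d$adjacency),
                           dimnames = dimnames(net$d$adjacency))
  diag(flat$adjacency) <- 1
  s2 <- preservation_statistics(net$d, flat, genes)
  expect_equal(unname(s2["avg_weight"]), 0.3, tolerance = 1e-12)
})

test_that("fast statistics equal the slow SVD-based oracle", {
  # modules that are structured in both cohorts: the leading eigenvalue is
  # well separated, where the capped power iteration is exact
  pair <- generate_cohort_pair(tiny_config(seed = 32))
  net <- cohort_nets(pair)
  for (mod in c("M1", "M2")) {
    genes <- names(pair$truth$true_assignment)[
      pair$truth$true_assignment == mod]
    fast <- preservation_statistics(net$d, net$t, genes)
    slow <- preservation_stats_oracle(net$d, net$t, genes)
    expect_equal(fast, slow, tolerance = 1e-6)
  }
})

test_that("statistics are invariant to gene and sample ordering", {
  pair <- generate_cohort_pair(tiny_config(seed = 33))
  net <- cohort_nets(pair)
  genes <- names(pair$truth$true_assignment)[
    pair$truth$true_assignment == "M2"]
  base <- preservation_statistics(net$d, net$t, genes)
  set.seed(1)
  shuffled <- preservation_statistics(net$d, net$t, sample(genes))
  expect_equal(base, shuffled, tolerance = 1e-9)
  net2 <- net
  net2$t$expr <- net$t$expr[, sample(ncol(net$t$expr))]
  expect_equal(preservation_statistics(net2$d, net2$t, genes), base,
               tolerance = 1e-9)
})

test_that("permutation p-values respect the estimator floor and detect the planted module", {
  pair <- generate_cohort_pair(tiny_config(seed = 34))
  net <- cohort_nets(pair)
  truth <- pair$truth$true_assignment
  assign <- structure(ifelse(truth == "background", "unassigned", truth),
                      class = "module_assignment")
  names(assign) <- names(truth)
  res <- preservation_permutation_test(net$d, net$t, assign, n_perm = 99,
                                       seed = 5)
  for (r in res) {
    expect_true(all(r$p_values >= 1 / 100 & r$p_values <= 1))
    expect_equal(r$n_permutations, 99)
    expect_identical(r$nonpreserved, all(r$p_values < 0.05))
  }
  # the destroyed module reaches the floor on the density-style statistics
  np <- pair$truth$nonpreserved_labels[1]
  expect_equal(unname(res[[np]]$p_values["avg_weight"]), 1 / 100)
  # preserved modules are not flagged
  for (m in setdiff(names(res), np)) expect_false(res[[m]]$nonpreserved)
})

test_that("the permutation test is deterministic given a seed", {
  pair <- generate_cohort_pair(tiny_config(seed = 35))
  net <- cohort_nets(pair)
  truth <- pair$truth$true_assignment
  assign <- structure(ifelse(truth == "background", "unassigned", truth),
                      class = "module_assignment")
  names(assign) <- names(truth)
  r1 <- preservation_permutation_test(net$d, net$t, assign, n_perm = 50, seed = 9)
  r2 <- preservation_permutation_test(net$d, net$t, assign, n_perm = 50, seed = 9)
  expect_identical(r1, r2)
  r3 <- preservation_permutation_test(net$d, net$t, assign, n_perm = 50, seed = 10)
  expect_false(identical(r1, r3))
})

test_that("non-preservation classification applies the all-seven rule", {
  fake <- function(label, p) {
    structure(list(module = label, size = 10,
                   observed = stats::setNames(rep(0.5, 7), paste0("s", 1:7)),
                   p_values = stats::setNames(p, paste0("s", 1:7)),
                   max_p = max(p), nonpreserved = all(p < 0.05),
                   n_permutations = 100), class = "preservation_result")
  }
  res <- list(
    a = fake("a", rep(0.01, 7)),
    b = fake("b", c(rep(0.001, 6), 0.2)),
    c = fake("c", rep(0.0499, 7))
  )
  expect_setequal(classify_nonpreserved(res), c("a", "c"))
  expect_identical(classify_nonpreserved(res, alpha = 0.01), character(0))
  expect_identical(classify_nonpreserved(list()), character(0))
  tab <- preservation_table(res)
  expect_equal(nrow(tab), 3)
  expect_identical(tab$max_p_printed[1], format_pvalue_truncated(0.01))
})

test_that("eigengene contributions match the exact eigendecomposition on separated spectra", {
  pair <- generate_cohort_pair(tiny_config(seed = 36))
  genes <- names(pair$truth$true_assignment)[
    pair$truth$true_assignment == "M1"]
  C <- stats::cor(t(pair$cohort_a[genes, ]))
  fast <- preservenet:::eigengene_contrib(C)
  es <- eigen(C, symmetric = TRUE)
  exact <- sqrt(es$values[1]) * es$vectors[, 1]
  if (sum(exact) < 0) exact <- -exact
  expect_equal(as.numeric(fast), as.numeric(exact), tolerance = 1e-5)
})

test_that("zero-variance members yield NaN statistics and p-value 1 with warning", {
  pair <- generate_cohort_pair(tiny_config(seed = 37))
  net <- cohort_nets(pair)
  genes <- names(pair$truth$true_assignment)[
    pair$truth$true_assignment == "M3"]
  # constant test adjacency for the whole universe: within-module degree has
  # zero variance, so cor_degree is NaN
  net$t$adjacency[, ] <- 0.2
  diag(net$t$adjacency) <- 1
  s <- preservation_statistics(net$d, net$t, genes)
  expect_true(is.nan(s["cor_degree"]))
  expect_equal(unname(s["avg_weight"]), 0.2, tolerance = 1e-12)
  assign <- structure(stats::setNames(rep("MX", length(genes)), genes),
                      class = "module_assignment")
  expect_warning(
    res <- preservation_permutation_test(net$d, net$t, assign, n_perm = 19,
                                         seed = 2),
    "NaN")
  expect_true(is.nan(res$MX$observed["cor_degree"]))
  expect_equal(unname(res$MX$p_values["cor_degree"]), 1)
})
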