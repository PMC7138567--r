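named_weight_matrix <- function(w) {
  n <- nrow(w)
  dimnames(w) <- list(sprintf("g%d", seq_len(n)), sprintf("g%d", seq_len(n)))
  diag(w) <- 1 # adjacency-style input; module_graph zeroes the diagonal
  w
}

# Expression whose genes reproduce any desired MM ordering is not needed for
# graph-metric tests; a shared-factor design keeps mm well defined.
graph_expr <- function(genes, seed = 1) {
  set.seed(seed)
  u <- rnorm(50)
  expr <- outer(rep(1, length(genes)), u) +
    matrix(rnorm(length(genes) * 50, sd = 0.5), length(genes))
  dimnames(expr) <- list(genes, sprintf("s%02d", 1:50))
  expr
}

test_that("star and path graphs give hand-enumerated centralities", {
  # unweighted star on 5 nodes (unit edge weights = unit costs)
  w <- matrix(0, 5, 5)
  w[1, 2:5] <- 1
  w[2:5, 1] <- 1
  g <- module_graph(named_weight_matrix(w), sprintf("g%d", 1:5))
  expr <- graph_expr(g$genes)
  eig <- module_eigengene(expr, g$genes)
  tab <- hub_scores(g, expr, eig)
  expect_equal(tab$betweenness, c(6, 0, 0, 0, 0)) # all C(4,2) pairs via center
  expect_equal(tab$closeness[1], 1 / 4)
  expect_equal(tab$closeness[2], 1 / (1 + 2 * 3), tolerance = 1e-12)
  expect_equal(sum(tab$pagerank), 1, tolerance = 1e-12)
  expect_equal(max(tab$kleinberg), 1)
  expect_equal(which.max(tab$kleinberg), 1L)

  # path a - b - c with unit costs
  w3 <- matrix(0, 3, 3)
  w3[1, 2] <- w3[2, 1] <- 1
  w3[2, 3] <- w3[3, 2] <- 1
  g3 <- module_graph(named_weight_matrix(w3), sprintf("g%d", 1:3))
  expr3 <- graph_expr(g3$genes)
  tab3 <- hub_scores(g3, expr3, module_eigengene(expr3, g3$genes))
  expect_equal(tab3$betweenness, c(0, 1, 0))
  expect_equal(tab3$closeness, c(1 / 3, 1 / 2, 1 / 3), tolerance = 1e-12)
})

test_that("a complete equal-weight graph ties every graph score and p = 0 with warning", {
  w <- matrix(0.4, 6, 6)
  g <- module_graph(named_weight_matrix(w), sprintf("g%d", 1:6))
  genes <- g$genes
  set.seed(3)
  u <- rnorm(40)
  expr <- outer(rep(0.8, 6), u) # identical profiles: mm ties too
  expr <- expr + matrix(rep(rnorm(40, sd = 0.2), each = 6), 6) # shared noise
  dimnames(expr) <- list(genes, sprintf("s%02d", 1:40))
  tab <- hub_scores(g, expr, module_eigengene(expr, genes))
  for (s in c("mm", "betweenness", "closeness", "pagerank", "kleinberg")) {
    expect_lt(diff(range(tab[[s]])), 1e-9)
  }
  expect_warning(pt <- hub_permutation_test(tab, n_perm = 50, seed = 1),
                 "tied")
  expect_true(all(pt$min_p == 0))
})

test_that("weighted betweenness and closeness match the path-enumeration oracle", {
  set.seed(17)
  for (n in c(5, 6, 7)) {
    for (rep in 1:3) {
      w <- matrix(0, n, n)
      w[upper.tri(w)] <- sample(c(0, round(runif(1, 0.1, 1), 2)),
                                sum(upper.tri(w)), replace = TRUE,
                                prob = c(0.3, 0.7))
      w <- w + t(w)
      # ensure connectivity via a ring
      for (i in seq_len(n)) {
        j <- i %% n + 1
        if (w[i, j] == 0) w[i, j] <- w[j, i] <- 0.5
      }
      g <- module_graph(named_weight_matrix(w), sprintf("g%d", 1:n))
      expr <- graph_expr(g$genes, seed = rep)
      tab <- hub_scores(g, expr, module_eigengene(expr, g$genes))
      costs <- g$weights # weight_as_cost default
      expect_equal(tab$betweenness, betweenness_oracle(costs), tolerance = 1e-10)
      expect_equal(tab$closeness, closeness_oracle(costs), tolerance = 1e-10)
    }
  }
})

test_that("strength interpretation inverts costs for path metrics", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[2, 3] <- w[3, 2] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.1
  gs <- module_graph(named_weight_matrix(w), sprintf("g%d", 1:3),
                     edge_interpretation = "weight_as_strength")
  expr <- graph_expr(gs$genes)
  tab <- hub_scores(gs, expr, module_eigengene(expr, gs$genes))
  # strong edges become cheap: paths route through the middle gene
  expect_equal(tab$betweenness[2], 1)
  costs <- 1 / gs$weights
  costs[gs$weights == 0] <- 0
  expect_equal(tab$closeness, closeness_oracle(costs), tolerance = 1e-10)
})

test_that("kleinberg scores agree with igraph's HITS implementation", {
  set.seed(23)
  w <- matrix(runif(49), 7, 7)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  g <- module_graph(named_weight_matrix(w), sprintf("g%d", 1:7))
  expr <- graph_expr(g$genes)
  tab <- hub_scores(g, expr, module_eigengene(expr, g$genes))
  ig <- igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  ref <- if ("hits_scores" %in% getNamespaceExports("igraph")) {
    igraph::hits_scores(ig, scale = TRUE)$hub
  } else {
    suppressWarnings(igraph::hub_score(ig, scale = TRUE)$vector)
  }
  expect_equal(tab$kleinberg, as.numeric(ref), tolerance = 1e-8)
})

test_that("label permutation equals score re-reading and the exact rank law", {
  set.seed(29)
  n <- 6
  w <- matrix(runif(n * n, 0.1, 1), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  g <- module_graph(named_weight_matrix(w), sprintf("g%d", 1:n))
  expr <- graph_expr(g$genes)
  tab <- hub_scores(g, expr, module_eigengene(expr, g$genes))
  obs <- as.matrix(tab[, c("mm", "betweenness", "closeness", "pagerank",
                           "kleinberg")])

  # relabelling the adjacency and recomputing = re-reading scores at the
  # label's new position (graph isomorphism), for every graph-based score
  for (rep in 1:5) {
    perm <- sample(n)
    wp <- g$weights[perm, perm]
    dimnames(wp) <- list(g$genes, g$genes)
    gp <- module_graph(named_weight_matrix(wp + diag(n)), g$genes)
    exprp <- expr[perm, ]
    rownames(exprp) <- g$genes
    tabp <- hub_scores(gp, exprp, module_eigengene(exprp, gp$genes))
    for (s in c("betweenness", "closeness", "pagerank", "kleinberg")) {
      expect_equal(tabp[[s]], tab[[s]][perm], tolerance = 1e-9)
    }
    expect_equal(abs(tabp$mm), abs(tab$mm[perm]), tolerance = 1e-9)
  }

  # exact rank law by full enumeration over all n! relabellings
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                 drop = FALSE]
  expect_equal(nrow(perms), factorial(n))
  for (s in c("mm", "pagerank")) {
    x <- obs[, s]
    p_enum <- vapply(seq_len(n), function(i) {
      mean(x[perms[, i]] > x[i])
    }, numeric(1))
    p_rank <- vapply(seq_len(n), function(i) sum(x > x[i]) / n, numeric(1))
    expect_equal(p_enum, p_rank, tolerance = 1e-12)
  }

  # the sampled permutation test approaches the exact rank p
  pt <- hub_permutation_test(tab, n_perm = 2000, seed = 7)
  for (s in c("mm", "betweenness", "pagerank")) {
    x <- obs[, s]
    p_rank <- vapply(seq_len(n), function(i) sum(x > x[i]) / n, numeric(1))
    se <- sqrt(pmax(p_rank * (1 - p_rank), 1e-4) / 2000)
    expect_true(all(abs(pt[[paste0("p_", s)]] - p_rank) <= 4 * se + 1e-9))
  }
  # a unique maximum always gets p = 0
  top <- which.max(obs[, "pagerank"])
  expect_equal(pt$p_pagerank[top], 0)
})

test_that("permutation testing is deterministic and flags by the any-method rule", {
  set.seed(31)
  w <- matrix(runif(25, 0.1, 1), 5, 5)
  w <- (w + t(w)) / 2
  g <- module_graph(named_weight_matrix(w), sprintf("g%d", 1:5))
  expr <- graph_expr(g$genes)
  tab <- hub_scores(g, expr, module_eigengene(expr, g$genes))
  p1 <- hub_permutation_test(tab, n_perm = 200, seed = 3)
  p2 <- hub_permutation_test(tab, n_perm = 200, seed = 3)
  expect_identical(p1, p2)
  expect_error(hub_permutation_test(tab, n_perm = 0), "n_perm")

  fake <- tab
  for (s in c("mm", "betweenness", "closeness", "pagerank", "kleinberg")) {
    fake[[paste0("p_", s)]] <- c(0.5, 0.5, 0.5, 0.5, 0.5)
  }
  fake$p_mm <- c(0.005, 0.5, 0.02, 0.5, 0.5)
  fake$p_pagerank <- c(0.5, 0.5, 0.001, 0.5, 0.5)
  fake$min_p <- pmin(fake$p_mm, fake$p_betweenness, fake$p_closeness,
                     fake$p_pagerank, fake$p_kleinberg)
  fake$significant <- fake$min_p < 0.01
  hubs <- significant_hubs(fake)
  expect_identical(hubs, c("g3", "g1")) # sorted by min p then gene ID
  expect_identical(significant_hubs(fake, alpha = 1e-4), character(0))
  expect_identical(significant_hubs(fake[0, ]), character(0))
})

test_that("disconnected module graphs warn and score per component", {
  w <- matrix(0, 6, 6)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  w[4, 5] <- w[5, 4] <- 0.5
  w[5, 6] <- w[6, 5] <- 0.5
  g <- module_graph(named_weight_matrix(w), sprintf("g%d", 1:6))
  expr <- graph_expr(g$genes)
  expect_warning(tab <- hub_scores(g, expr, module_eigengene(expr, g$genes)),
                 "disconnected")
  expect_equal(sum(tab$pagerank), 1, tolerance = 1e-12)
  expect_equal(tab$closeness[2], 1 / 1, tolerance = 1e-12) # reachable: g1, g3 at cost 0.5
})

test_that("threshold graph export counts edges under the stated convention", {
  set.seed(5)
  n <- 10
  am <- matrix(runif(n * n, 0.01, 0.9), n, n)
  am <- (am + t(am)) / 2
  diag(am) <- 1
  dimnames(am) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  path <- tempfile(fileext = ".tsv")
  out <- export_threshold_graph(am, cutoff = 0.5, path = path)
  expect_equal(out$total_pairs, n * (n + 1) / 2)
  expect_equal(out$kept, sum(am[upper.tri(am)] > 0.5))
  lines <- readLines(path)
  expect_match(lines[1], sprintf("kept %d of %d edges", out$kept, out$total_pairs))
  expect_equal(length(lines), out$kept + 2) # summary + header + edges

  expect_equal(export_threshold_graph(am, cutoff = 1)$kept, 0)
  all_kept <- export_threshold_graph(am, cutoff = 0)
  expect_equal(all_kept$kept, n * (n - 1) / 2)
  expect_error(export_threshold_graph(am, cutoff = 1.2), "cutoff")
})
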