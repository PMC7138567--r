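# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are deliberately naive (loops, enumeration) and share no
# code with the package implementations they check.

# Block-structured similarity matrix: within-block value `within`,
# between-block `between`, unit diagonal. Returned with gene names and the
# true block labels as an attribute.
make_block_similarity <- function(sizes, within = 0.8, between = 0.05) {
  n <- sum(sizes)
  genes <- sprintf("b%03d", seq_len(n))
  m <- matrix(between, n, n, dimnames = list(genes, genes))
  labels <- rep(sprintf("B%d", seq_along(sizes)), sizes)
  for (b in unique(labels)) {
    idx <- which(labels == b)
    m[idx, idx] <- within
  }
  diag(m) <- 1
  attr(m, "blocks") <- stats::setNames(labels, genes)
  m
}

# Triple-loop TOM oracle.
tom_oracle <- function(am) {
  a <- am
  diag(a) <- 0
  n <- nrow(a)
  out <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(am)
  out
}

# All-pairs shortest path distances and path counts by exhaustive
# enumeration of simple paths (n <= 8). costs: symmetric matrix, 0 = absent
# edge.
enumerate_paths <- function(costs) {
  n <- nrow(costs)
  best <- matrix(Inf, n, n)
  npaths <- matrix(0, n, n)
  through <- array(0, c(n, n, n)) # shortest paths s-t passing interior v
  explore <- function(path, cost, target) {
    v <- path[length(path)]
    if (v == target) {
      s <- path[1]
      if (cost < best[s, target] - 1e-12) {
        best[s, target] <<- cost
        npaths[s, target] <<- 1
        through[s, target, ] <<- 0
        for (w in setdiff(path, c(s, target))) through[s, target, w] <<- 1
      } else if (abs(cost - best[s, target]) <= 1e-12) {
        npaths[s, target] <<- npaths[s, target] + 1
        for (w in setdiff(path, c(s, target))) {
          through[s, target, w] <<- through[s, target, w] + 1
        }
      }
      return(invisible())
    }
    for (w in seq_len(n)) {
      if (w %in% path || costs[v, w] == 0) next
      explore(c(path, w), cost + costs[v, w], target)
    }
  }
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s != t) explore(s, 0, t)
    }
  }
  list(dist = best, npaths = npaths, through = through)
}

# Unnormalized betweenness (Brandes definition) from the path enumeration.
betweenness_oracle <- function(costs) {
  e <- enumerate_paths(costs)
  n <- nrow(costs)
  out <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || e$npaths[s, t] == 0) next
        acc <- acc + e$through[s, t, v] / e$npaths[s, t]
      }
    }
    out[v] <- acc
  }
  out
}

# Unnormalized closeness 1 / sum(dist) from the path enumeration
# (connected graphs only).
closeness_oracle <- function(costs) {
  d <- enumerate_paths(costs)$dist
  diag(d) <- 0
  1 / rowSums(d)
}

# Upper-tail hypergeometric P(overlap >= k) by direct combinatorial sum.
hyper_tail_oracle <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Two-sided Fisher exact p by enumeration over the hypergeometric support,
# probability-mass definition with the conventional 1e-7 relative fudge.
fisher_two_sided_oracle <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  support <- max(0, k - m2):min(k, m1)
  probs <- vapply(support, function(x) {
    choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small, fast synthetic configuration for unit tests (not the frozen study
# conditions; those are exercised in the acceptance suite).
tiny_config <- function(seed = 1, ...) {
  args <- list(
    n_genes = 150L, n_samples_a = 60L, n_samples_b = 60L,
    module_sizes = c(60L, 25L, 30L), n_nonpreserved = 1L,
    loading_range = c(0.5, 0.8), hub_loading = 0.95, noise_sd = 0.5,
    n_hubs_per_module = 1L, seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}
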