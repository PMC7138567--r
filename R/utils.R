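# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a reproducible per-stage child seed from a master seed
#'
#' A single master seed fans out to per-stage seeds via a small string hash,
#' so any stage can be re-run in isolation and reproduce the full-pipeline
#' result. Seeds stay below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  out <- ((abs(master) %% 1e9) * 2038 + h * 1009) %% 2147483646
  as.integer(out) + 1L
}

#' Format a p-value with truncation to significant figures
#'
#' Permutation p-values are reported at three significant figures with the
#' mantissa truncated (not rounded), so the estimator floor
#' 1/(n_perm + 1) = 1/10001 prints as "9.99E-5".
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param sig number of significant figures (default 3).
#' @return character vector.
#' @export
format_pvalue_truncated <- function(p, sig = 3) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x <= 0) return("0")
    if (x >= 1) return("1")
    e <- floor(log10(x))
    man <- x / 10^e
    man <- floor(man * 10^(sig - 1)) / 10^(sig - 1)
    if (man >= 10) { # guard against floating point spill
      man <- man / 10
      e <- e + 1
    }
    if (e >= -3) {
      # plain decimal for moderate p, truncated at the same precision
      val <- man * 10^e
      format(val, scientific = FALSE, trim = TRUE)
    } else {
      paste0(formatC(man, format = "f", digits = sig - 1), "E", e)
    }
  }, character(1))
}

#' Adjusted Rand index between two labelings
#'
#' Used to quantify planted-module recovery; agrees with the standard
#' Hubert-Arabie definition.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Count gene pairs in a module under a stated convention
#'
#' Graph exports report "kept X of Y edges"; Y depends on the pair-counting
#' convention. `upper_with_diagonal` counts n(n+1)/2 unordered pairs
#' including self-pairs, `ordered` counts n^2, `unordered` counts n(n-1)/2.
#'
#' @param n number of genes (nodes).
#' @param convention one of "upper_with_diagonal", "ordered", "unordered".
#' @return integer-valued numeric pair count.
#' @export
pair_count <- function(n, convention = c("upper_with_diagonal", "ordered", "unordered")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  switch(convention,
    upper_with_diagonal = n * (n + 1) / 2,
    ordered = n * n,
    unordered = n * (n - 1) / 2
  )
}

# Stop with a configuration error naming the violated constraint.
config_error <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Check symmetric numeric matrix with dimnames.
check_square_named <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) config_error("%s must be a numeric matrix", what)
  if (nrow(m) != ncol(m)) config_error("%s must be square", what)
  if (is.null(rownames(m))) config_error("%s must carry gene identifiers as dimnames", what)
  invisible(TRUE)
}
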