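#' Configuration for the synthetic two-cohort generator
#'
#' The generator emulates the data structure assumed by blood co-expression
#' network studies: two cohorts sharing a gene universe, block-structured
#' modules driven by latent per-sample eigengene factors with per-gene
#' loadings (hubs carry the highest loading), and a subset of modules whose
#' correlation structure is destroyed (or perturbed) in the second cohort.
#'
#' Defaults encode the study conditions used throughout the package's
#' validation: four modules of sizes 320/100/90/120 plus 170 background
#' genes, 150 samples per cohort, non-hub loadings uniform on (0.5, 0.8),
#' hub loading 0.95, noise standard deviation 0.5, one planted hub per
#' module and one non-preserved module ("M4", 120 genes). The size
#' distribution is deliberately heavy-tailed with one dominant module, the
#' shape real co-expression networks show: the preservation permutation
#' null draws random gene sets from the shared universe, and its
#' contribution-based statistics are only well-behaved when one preserved
#' block dominates the first principal component of those random sets in
#' both cohorts (with evenly sized blocks the top eigenspace of a null draw
#' is near-degenerate and sign-mixing inflates the null's left tail). The
#' non-preserved module is kept well below the dominant one for the same
#' reason, and above 100 genes so hub recovery is assessed at a realistic
#' module size.
#'
#' @param n_genes total genes in the shared universe.
#' @param n_samples_a,n_samples_b samples per cohort.
#' @param module_sizes integer vector of planted module sizes; their sum must
#'   not exceed `n_genes` (remaining genes are pure-noise background).
#' @param n_nonpreserved how many modules (taken from the back of
#'   `module_sizes`, i.e. the smallest blocks) lose their correlation
#'   structure in cohort B.
#' @param loading_range length-2 numeric in (0, 1]: per-gene loadings are
#'   drawn uniformly from this interval.
#' @param hub_loading loading assigned to designated hub genes; must be at
#'   least the upper end of `loading_range`.
#' @param noise_sd standard deviation of the additive gene-level noise (> 0);
#'   background genes are pure noise with this standard deviation.
#' @param n_hubs_per_module designated hubs per module.
#' @param nonpreserved_mode `"zero"` (loadings zeroed in cohort B: complete
#'   destruction) or `"shuffle"` (a fraction of loadings permuted across the
#'   module's genes: partial perturbation, for power studies).
#' @param shuffle_fraction fraction of loadings permuted under `"shuffle"`.
#' @param n_gwas number of synthetic "GWAS" genes.
#' @param gwas_nonpreserved_fraction fraction of GWAS genes placed inside
#'   non-preserved modules.
#' @param n_mirnas number of synthetic disease miRNA identifiers.
#' @param seed integer seed; all generator output is deterministic given it.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 800L,
                             n_samples_a = 150L,
                             n_samples_b = 150L,
                             module_sizes = c(320L, 100L, 90L, 120L),
                             n_nonpreserved = 1L,
                             loading_range = c(0.5, 0.8),
                             hub_loading = 0.95,
                             noise_sd = 0.5,
                             n_hubs_per_module = 1L,
                             nonpreserved_mode = c("zero", "shuffle"),
                             shuffle_fraction = 0.5,
                             n_gwas = 10L,
                             gwas_nonpreserved_fraction = 0.7,
                             n_mirnas = 8L,
                             seed = 1L) {
  nonpreserved_mode <- match.arg(nonpreserved_mode)
  if (length(module_sizes) < 1L || any(module_sizes < 2))
    config_error("module_sizes must contain counts >= 2")
  if (sum(module_sizes) > n_genes)
    config_error("sum(module_sizes) = %d exceeds n_genes = %d",
                 sum(module_sizes), n_genes)
  if (n_nonpreserved > length(module_sizes))
    config_error("n_nonpreserved = %d exceeds the number of modules (%d)",
                 n_nonpreserved, length(module_sizes))
  if (length(loading_range) != 2L || loading_range[1] > loading_range[2] ||
      loading_range[1] <= 0 || loading_range[2] > 1)
    config_error("loading_range must be an interval within (0, 1]")
  if (hub_loading < loading_range[2] || hub_loading > 1)
    config_error("hub_loading must satisfy loading_range[2] <= hub_loading <= 1")
  if (noise_sd <= 0) config_error("noise_sd must be > 0")
  if (n_hubs_per_module < 0 || any(n_hubs_per_module > module_sizes))
    config_error("n_hubs_per_module must be <= every module size")
  if (min(n_samples_a, n_samples_b) < 3) config_error("each cohort needs >= 3 samples")
  if (shuffle_fraction < 0 || shuffle_fraction > 1)
    config_error("shuffle_fraction must lie in [0, 1]")
  structure(list(
    n_genes = as.integer(n_genes),
    n_samples_a = as.integer(n_samples_a),
    n_samples_b = as.integer(n_samples_b),
    module_sizes = as.integer(module_sizes),
    n_nonpreserved = as.integer(n_nonpreserved),
    loading_range = as.numeric(loading_range),
    hub_loading = as.numeric(hub_loading),
    noise_sd = as.numeric(noise_sd),
    n_hubs_per_module = as.integer(n_hubs_per_module),
    nonpreserved_mode = nonpreserved_mode,
    shuffle_fraction = as.numeric(shuffle_fraction),
    n_gwas = as.integer(n_gwas),
    gwas_nonpreserved_fraction = as.numeric(gwas_nonpreserved_fraction),
    n_mirnas = as.integer(n_mirnas),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a two-cohort expression pair with known ground truth
#'
#' Each module m is driven by a latent standard-normal factor u_m (one value
#' per sample, drawn independently per cohort — preservation is a property
#' of correlation structure, not of sample-level values). Gene i of module m
#' has expression `w_i * u_m + eps`, `eps ~ N(0, noise_sd^2)`, with loading
#' `w_i` uniform on `loading_range` and `w_i = hub_loading` for designated
#' hubs. Background genes are pure noise. For non-preserved modules the
#' cohort-B expression is regenerated with loadings zeroed (mode `"zero"`)
#' or with a fraction of loadings permuted (mode `"shuffle"`). Values are
#' stored unstandardized; standardization happens inside consumers.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `cohort_a`, `cohort_b` (genes x samples
#'   numeric matrices with gene/sample dimnames and a `cohort` attribute)
#'   and `truth` (list: `true_assignment` named gene -> module/"background",
#'   `nonpreserved_labels`, `hub_genes`, `loadings`, `gwas_genes`,
#'   `disease_mirnas`).
#' @export
generate_cohort_pair <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config_error("config must be created by synthetic_config()")
  with_seed(config$seed, {
    n <- config$n_genes
    genes <- sprintf("g%04d", seq_len(n))
    k <- length(config$module_sizes)
    labels <- sprintf("M%d", seq_len(k))
    assignment <- rep("background", n)
    names(assignment) <- genes
    idx <- 1L
    module_genes <- vector("list", k)
    names(module_genes) <- labels
    for (m in seq_len(k)) {
      sz <- config$module_sizes[m]
      module_genes[[m]] <- genes[idx:(idx + sz - 1L)]
      assignment[idx:(idx + sz - 1L)] <- labels[m]
      idx <- idx + sz
    }
    nonpreserved <- if (config$n_nonpreserved > 0) {
      utils::tail(labels, config$n_nonpreserved)
    } else character(0)

    loadings <- stats::setNames(numeric(n), genes)
    hub_genes <- vector("list", k)
    names(hub_genes) <- labels
    for (m in seq_len(k)) {
      gs <- module_genes[[m]]
      loadings[gs] <- stats::runif(length(gs), config$loading_range[1],
                                   config$loading_range[2])
      if (config$n_hubs_per_module > 0) {
        hubs <- sample(gs, config$n_hubs_per_module)
        loadings[hubs] <- config$hub_loading
        hub_genes[[m]] <- sort(hubs)
      } else {
        hub_genes[[m]] <- character(0)
      }
    }

    make_cohort <- function(n_samples, cohort, destroyed) {
      expr <- matrix(stats::rnorm(n * n_samples, sd = config$noise_sd),
                     nrow = n, ncol = n_samples,
                     dimnames = list(genes, sprintf("%s_s%03d", cohort,
                                                    seq_len(n_samples))))
      for (m in seq_len(k)) {
        gs <- module_genes[[m]]
        w <- loadings[gs]
        if (labels[m] %in% destroyed) {
          if (config$nonpreserved_mode == "zero") {
            next # loadings zeroed: pure noise already in place
          } else {
            n_shuf <- round(config$shuffle_fraction * length(gs))
            if (n_shuf >= 2) {
              pick <- sample(seq_along(gs), n_shuf)
              w[pick] <- w[sample(pick)]
            }
          }
        }
        u <- stats::rnorm(n_samples)
        expr[gs, ] <- expr[gs, ] + outer(w, u)
      }
      attr(expr, "cohort") <- cohort
      expr
    }

    cohort_a <- make_cohort(config$n_samples_a, "A", character(0))
    cohort_b <- make_cohort(config$n_samples_b, "B", nonpreserved)

    np_pool <- unlist(module_genes[nonpreserved], use.names = FALSE)
    other_pool <- setdiff(genes, np_pool)
    n_in <- min(round(config$gwas_nonpreserved_fraction * config$n_gwas),
                length(np_pool))
    gwas <- character(0)
    if (config$n_gwas > 0) {
      gwas <- c(if (n_in > 0 && length(np_pool) > 0) sample(np_pool, n_in),
                sample(other_pool, config$n_gwas - n_in))
      gwas <- sort(gwas)
    }
    mirnas <- sprintf("hsa-mir-%03d", seq_len(config$n_mirnas))

    list(
      cohort_a = cohort_a,
      cohort_b = cohort_b,
      truth = list(
        true_assignment = assignment,
        nonpreserved_labels = nonpreserved,
        hub_genes = hub_genes,
        loadings = loadings,
        gwas_genes = gwas,
        disease_mirnas = mirnas
      )
    )
  })
}

#' Generate a synthetic gene-set library with planted enrichment
#'
#' A local stand-in for curated GO/KEGG/TF libraries: a known subset of the
#' sets is constructed to overlap planted modules (`enriched_fraction` of
#' each such set is drawn from one module, cycling over modules), the rest
#' is drawn uniformly from the gene universe.
#'
#' @param truth the `truth` element of [generate_cohort_pair()].
#' @param n_sets number of sets; half (rounded up) are module-enriched when
#'   `enriched_fraction > 0`.
#' @param enriched_fraction fraction of each enriched set drawn from its
#'   target module, in \[0, 1\].
#' @param set_size genes per set.
#' @param seed integer seed.
#' @return a `gene_set_library`: list with `sets` (named list of gene
#'   vectors), `source = "synthetic"` and `enriched_for` (named character,
#'   NA for background sets).
#' @export
generate_gene_set_library <- function(truth, n_sets, enriched_fraction,
                                      set_size = 10L, seed = 1L) {
  universe <- names(truth$true_assignment)
  if (length(universe) == 0) config_error("empty gene universe")
  if (enriched_fraction < 0 || enriched_fraction > 1)
    config_error("enriched_fraction must lie in [0, 1]")
  modules <- setdiff(unique(truth$true_assignment), "background")
  with_seed(seed, {
    sets <- list()
    enriched_for <- character(0)
    n_enriched <- if (enriched_fraction > 0 && length(modules) > 0)
      ceiling(n_sets / 2) else 0L
    for (i in seq_len(n_sets)) {
      nm <- sprintf("SET%03d", i)
      if (i <= n_enriched) {
        mod <- modules[(i - 1L) %% length(modules) + 1L]
        mod_genes <- universe[truth$true_assignment == mod]
        k_in <- min(round(enriched_fraction * set_size), length(mod_genes))
        inside <- sample(mod_genes, k_in)
        outside <- sample(setdiff(universe, inside), set_size - k_in)
        sets[[nm]] <- sort(c(inside, outside))
        enriched_for[nm] <- mod
      } else {
        sets[[nm]] <- sort(sample(universe, min(set_size, length(universe))))
        enriched_for[nm] <- NA_character_
      }
    }
    structure(list(sets = sets, source = "synthetic",
                   enriched_for = enriched_for),
              class = "gene_set_library")
  })
}

#' Generate synthetic gene-SNP and SNP-miRNA annotation tables
#'
#' Local stand-ins for eQTL (gene, SNP, p-value, frequency) and
#' SNP-to-miRNA join tables. Planted rows pass the downstream filters
#' (p < 1e-4, frequency > 0.10) and join to disease miRNAs; decoy rows each
#' fail exactly one filter (p equal to 1e-4, frequency equal to 0.10, or a
#' miRNA absent from the disease list), exercising the strict inequalities.
#'
#' @param truth the `truth` element of [generate_cohort_pair()].
#' @param seed integer seed.
#' @param n_planted_per_module planted passing rows per non-preserved module.
#' @return list with `gene_snp` (data.frame: gene, snp_id, p_value,
#'   frequency), `snp_mirna` (data.frame: snp_id, mirna_id) and
#'   `expected_hits` (data.frame of rows that must survive the full
#'   filter-join against the non-preserved module genes).
#' @export
generate_variant_tables <- function(truth, seed = 1L, n_planted_per_module = 3L) {
  universe <- names(truth$true_assignment)
  if (length(universe) < 1) config_error("truth must contain at least one gene")
  with_seed(seed, {
    np_mods <- truth$nonpreserved_labels
    mirnas <- truth$disease_mirnas
    gene_snp <- data.frame(gene = character(0), snp_id = character(0),
                           p_value = numeric(0), frequency = numeric(0))
    snp_mirna <- data.frame(snp_id = character(0), mirna_id = character(0))
    expected <- data.frame(gene = character(0), snp_id = character(0),
                           mirna_id = character(0))
    snp_i <- 0L
    new_snp <- function() {
      snp_i <<- snp_i + 1L
      sprintf("rs%06d", snp_i)
    }
    for (mod in np_mods) {
      mod_genes <- universe[truth$true_assignment == mod]
      planted <- sample(mod_genes, min(n_planted_per_module, length(mod_genes)))
      for (g in planted) {
        snp <- new_snp()
        mir <- sample(mirnas, 1L)
        gene_snp <- rbind(gene_snp, data.frame(
          gene = g, snp_id = snp,
          p_value = stats::runif(1, 1e-8, 5e-5),
          frequency = stats::runif(1, 0.15, 0.45)))
        snp_mirna <- rbind(snp_mirna, data.frame(snp_id = snp, mirna_id = mir))
        expected <- rbind(expected, data.frame(gene = g, snp_id = snp,
                                               mirna_id = mir))
      }
      # decoys, one failed filter each
      decoy_genes <- sample(mod_genes, min(3L, length(mod_genes)))
      snp <- new_snp() # p exactly at threshold (strict < excludes it)
      gene_snp <- rbind(gene_snp, data.frame(
        gene = decoy_genes[1], snp_id = snp, p_value = 1e-4, frequency = 0.3))
      snp_mirna <- rbind(snp_mirna, data.frame(snp_id = snp,
                                               mirna_id = sample(mirnas, 1L)))
      snp <- new_snp() # frequency exactly at threshold (strict > excludes it)
      gene_snp <- rbind(gene_snp, data.frame(
        gene = decoy_genes[min(2L, length(decoy_genes))], snp_id = snp,
        p_value = 1e-6, frequency = 0.10))
      snp_mirna <- rbind(snp_mirna, data.frame(snp_id = snp,
                                               mirna_id = sample(mirnas, 1L)))
      snp <- new_snp() # passes filters but maps to a non-disease miRNA
      gene_snp <- rbind(gene_snp, data.frame(
        gene = decoy_genes[min(3L, length(decoy_genes))], snp_id = snp,
        p_value = 1e-6, frequency = 0.3))
      snp_mirna <- rbind(snp_mirna, data.frame(snp_id = snp,
                                               mirna_id = "hsa-mir-none"))
    }
    # background rows on genes outside non-preserved modules
    bg_genes <- universe[!(truth$true_assignment %in% np_mods)]
    for (g in sample(bg_genes, min(5L, length(bg_genes)))) {
      snp <- new_snp()
      gene_snp <- rbind(gene_snp, data.frame(
        gene = g, snp_id = snp, p_value = stats::runif(1, 1e-8, 5e-5),
        frequency = stats::runif(1, 0.15, 0.45)))
      snp_mirna <- rbind(snp_mirna, data.frame(snp_id = snp,
                                               mirna_id = sample(mirnas, 1L)))
    }
    list(gene_snp = gene_snp, snp_mirna = snp_mirna, expected_hits = expected)
  })
}

#' Write an expression matrix as TSV (first column `gene_id`)
#' @param expr genes x samples numeric matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#' @param path TSV path with a `gene_id` first column.
#' @return genes x samples numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") config_error("expected first column 'gene_id' in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write ground truth as JSON
#' @param truth the `truth` element of [generate_cohort_pair()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
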