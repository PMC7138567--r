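#' Pipeline configuration
#'
#' All defaults equal the stated analysis parameters: scale-free fit target
#' 0.85 over powers 1..20, deep split 3, minimum module size 10, merge cut
#' height 0.05, 10,000 preservation permutations at alpha 0.05 (alternative
#' "less", both directions), 1000 hub relabellings at alpha 0.01. Input is
#' either a synthetic generator configuration or two cohort TSV paths.
#'
#' @param synthetic a [synthetic_config()], or NULL when reading files.
#' @param cohort_a_path,cohort_b_path expression TSV paths (ignored when
#'   `synthetic` is given).
#' @param low_expression_fraction bottom mean-expression fraction removed
#'   before network construction (default 0.05 for file input, 0 for
#'   synthetic input whose values are centered at zero by construction).
#' @param powers soft-threshold powers to scan.
#' @param r2_target scale-free fit target.
#' @param network_type `"unsigned"` or `"signed"`.
#' @param n_bins connectivity bins for the scale-free fit.
#' @param deep_split,min_module_size,merge_cut_height,kmeans_max_iter module
#'   detection parameters.
#' @param preservation_n_perm,preservation_alpha,direction preservation test
#'   parameters; `direction` is `"both"`, `"ab"` (A modules tested in B) or
#'   `"ba"`.
#' @param hub_n_perm,hub_alpha,edge_interpretation hub test parameters.
#' @param gmt_path,gwas_path,gene_snp_path,snp_mirna_path,mirna_path optional
#'   annotation inputs (generated internally for synthetic runs when NULL).
#' @param seed master seed; per-stage child seeds are derived from it.
#' @param output_dir directory for artifacts, or NULL to skip writing.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL,
                            cohort_a_path = NULL,
                            cohort_b_path = NULL,
                            low_expression_fraction = NULL,
                            powers = 1:20,
                            r2_target = 0.85,
                            network_type = c("unsigned", "signed"),
                            n_bins = 10,
                            deep_split = 3,
                            min_module_size = 10,
                            merge_cut_height = 0.05,
                            kmeans_max_iter = 30,
                            preservation_n_perm = 10000,
                            preservation_alpha = 0.05,
                            direction = c("both", "ab", "ba"),
                            hub_n_perm = 1000,
                            hub_alpha = 0.01,
                            edge_interpretation = c("weight_as_cost",
                                                    "weight_as_strength"),
                            gmt_path = NULL,
                            gwas_path = NULL,
                            gene_snp_path = NULL,
                            snp_mirna_path = NULL,
                            mirna_path = NULL,
                            seed = 1L,
                            output_dir = NULL) {
  network_type <- match.arg(network_type)
  direction <- match.arg(direction)
  edge_interpretation <- match.arg(edge_interpretation)
  if (is.null(synthetic) && (is.null(cohort_a_path) || is.null(cohort_b_path)))
    config_error("either a synthetic config or two cohort TSV paths are required")
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config"))
    config_error("synthetic must be built by synthetic_config()")
  if (is.null(low_expression_fraction))
    low_expression_fraction <- if (is.null(synthetic)) 0.05 else 0
  if (low_expression_fraction < 0 || low_expression_fraction >= 1)
    config_error("low_expression_fraction must lie in [0, 1)")
  if (r2_target <= 0 || r2_target > 1) config_error("r2_target must lie in (0, 1]")
  if (preservation_alpha <= 0 || preservation_alpha >= 1 ||
      hub_alpha <= 0 || hub_alpha >= 1)
    config_error("alpha thresholds must lie in (0, 1)")
  if (preservation_n_perm < 1 || hub_n_perm < 1)
    config_error("permutation counts must be >= 1")
  structure(list(
    synthetic = synthetic, cohort_a_path = cohort_a_path,
    cohort_b_path = cohort_b_path,
    low_expression_fraction = low_expression_fraction,
    powers = powers, r2_target = r2_target, network_type = network_type,
    n_bins = n_bins, deep_split = deep_split,
    min_module_size = min_module_size, merge_cut_height = merge_cut_height,
    kmeans_max_iter = kmeans_max_iter,
    preservation_n_perm = preservation_n_perm,
    preservation_alpha = preservation_alpha, direction = direction,
    hub_n_perm = hub_n_perm, hub_alpha = hub_alpha,
    edge_interpretation = edge_interpretation,
    gmt_path = gmt_path, gwas_path = gwas_path,
    gene_snp_path = gene_snp_path, snp_mirna_path = snp_mirna_path,
    mirna_path = mirna_path,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected. The `synthetic` key, if present, is a mapping
#' of [synthetic_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    config_error("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(raw$synthetic)) {
    syn_known <- names(formals(synthetic_config))
    syn_unknown <- setdiff(names(raw$synthetic), syn_known)
    if (length(syn_unknown) > 0)
      config_error("unknown synthetic key(s): %s", paste(syn_unknown, collapse = ", "))
    if (!is.null(raw$synthetic$module_sizes))
      raw$synthetic$module_sizes <- unlist(raw$synthetic$module_sizes)
    if (!is.null(raw$synthetic$loading_range))
      raw$synthetic$loading_range <- unlist(raw$synthetic$loading_range)
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  }
  do.call(pipeline_config, raw)
}

# Network construction + module detection for one cohort.
build_cohort_network <- function(expr, config) {
  cm <- correlation_matrix(expr)
  scan <- soft_threshold_scan(cm, powers = config$powers, n_bins = config$n_bins,
                              network_type = config$network_type,
                              r2_target = config$r2_target)
  power <- scan$chosen_power
  power_fallback <- FALSE
  if (is.na(power)) {
    # no power reached the target: use the best-fitting power and record it
    power <- scan$fit$power[which.max(scan$fit$signed_r2)]
    power_fallback <- TRUE
  }
  am <- adjacency(cm, power, config$network_type)
  tom <- topological_overlap(am)
  dend <- hierarchical_tree(tom)
  assign0 <- dynamic_hybrid_cut(dend, tom, deep_split = config$deep_split,
                                min_module_size = config$min_module_size)
  assign <- assign0
  if (length(module_labels(assign)) > 0) {
    assign <- merge_close_modules(assign, expr,
                                  cut_height = config$merge_cut_height)
    assign <- kmeans_refine(assign, expr, max_iter = config$kmeans_max_iter)
  }
  list(expr = expr, correlation = cm, adjacency = am, tom = tom,
       soft_threshold = scan, power = power, power_fallback = power_fallback,
       assignment = assign)
}

# Preservation + hub analysis for one direction (modules of `disc` tested
# in `test`).
run_direction <- function(disc, test, config, seed_tag) {
  pres <- preservation_permutation_test(
    list(expr = disc$expr, adjacency = disc$adjacency),
    list(expr = test$expr, adjacency = test$adjacency),
    disc$assignment,
    n_perm = config$preservation_n_perm,
    alternative = "less",
    alpha = config$preservation_alpha,
    seed = child_seed(config$seed, paste0("preserve_", seed_tag)),
    min_size = config$min_module_size)
  nonpreserved <- classify_nonpreserved(pres, alpha = config$preservation_alpha)
  hubs <- list()
  for (lab in nonpreserved) {
    genes <- names(disc$assignment)[disc$assignment == lab]
    g <- module_graph(disc$adjacency, genes,
                      edge_interpretation = config$edge_interpretation)
    eig <- module_eigengene(disc$expr, genes)
    tab <- hub_scores(g, disc$expr, eig)
    tab <- hub_permutation_test(
      tab, n_perm = config$hub_n_perm,
      seed = child_seed(config$seed, paste0("hubs_", seed_tag, "_", lab)),
      alpha = config$hub_alpha)
    hubs[[lab]] <- tab
  }
  list(preservation = pres, nonpreserved = nonpreserved, hubs = hubs)
}

#' Run the full two-cohort analysis
#'
#' Executes (optional) low-expression filtering, per-cohort network
#' construction with per-cohort soft powers, module detection with eigengene
#' merging and k-means refinement, preservation permutation testing in the
#' configured direction(s), hub scoring with label-permutation significance
#' in every non-preserved module, and — when annotation inputs are available
#' or the run is synthetic — over-representation, GWAS-enrichment and
#' SNP/miRNA join statistics. Re-running with the same configuration and
#' seed reproduces the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return a report bundle (list) with elements `cohorts`, `directions`,
#'   `annotation`, `truth` (synthetic runs only) and `metadata`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config_error("config must be built by pipeline_config()")
  stage <- "input"
  bundle <- tryCatch({
    truth <- NULL
    if (!is.null(config$synthetic)) {
      pair <- generate_cohort_pair(config$synthetic)
      expr_a <- pair$cohort_a
      expr_b <- pair$cohort_b
      truth <- pair$truth
    } else {
      expr_a <- read_expression_tsv(config$cohort_a_path)
      expr_b <- read_expression_tsv(config$cohort_b_path)
    }

    stage <- "preprocessing"
    if (config$low_expression_fraction > 0) {
      expr_a <- filter_low_expression(expr_a, config$low_expression_fraction)
      expr_b <- filter_low_expression(expr_b, config$low_expression_fraction)
    }
    shared <- intersect(rownames(expr_a), rownames(expr_b))
    if (length(shared) < config$min_module_size)
      config_error("gene universes overlap by fewer than min_module_size genes")
    expr_a <- expr_a[shared, , drop = FALSE]
    expr_b <- expr_b[shared, , drop = FALSE]

    stage <- "network_construction"
    net_a <- build_cohort_network(expr_a, config)
    net_b <- build_cohort_network(expr_b, config)

    stage <- "module_preservation"
    directions <- list()
    if (config$direction %in% c("both", "ab"))
      directions$ab <- run_direction(net_a, net_b, config, "ab")
    if (config$direction %in% c("both", "ba"))
      directions$ba <- run_direction(net_b, net_a, config, "ba")

    stage <- "annotation"
    annotation <- NULL
    lib <- NULL
    gwas <- NULL
    variant <- NULL
    mirnas <- NULL
    if (!is.null(config$gmt_path)) lib <- read_gmt(config$gmt_path)
    if (!is.null(config$gwas_path)) gwas <- readLines(config$gwas_path)
    if (!is.null(config$gene_snp_path) && !is.null(config$snp_mirna_path)) {
      variant <- list(
        gene_snp = utils::read.delim(config$gene_snp_path, stringsAsFactors = FALSE),
        snp_mirna = utils::read.delim(config$snp_mirna_path, stringsAsFactors = FALSE))
    }
    if (!is.null(config$mirna_path)) mirnas <- readLines(config$mirna_path)
    if (!is.null(truth)) {
      if (is.null(lib))
        lib <- generate_gene_set_library(truth, n_sets = 20,
                                         enriched_fraction = 0.8,
                                         seed = child_seed(config$seed, "gmt"))
      if (is.null(gwas)) gwas <- truth$gwas_genes
      if (is.null(variant))
        variant <- generate_variant_tables(truth,
                                           seed = child_seed(config$seed, "variants"))
      if (is.null(mirnas)) mirnas <- truth$disease_mirnas
    }
    if (!is.null(lib) || !is.null(gwas) || !is.null(variant)) {
      annotation <- list()
      background <- shared
      nets <- list(ab = net_a, ba = net_b)
      for (dir in names(directions)) {
        net <- nets[[dir]]
        dir_ann <- list()
        for (lab in directions[[dir]]$nonpreserved) {
          genes <- names(net$assignment)[net$assignment == lab]
          entry <- list()
          if (!is.null(lib))
            entry$enrichment <- overrepresentation_test(genes, lib, background)
          if (!is.null(variant) && !is.null(mirnas))
            entry$snp_hits <- snp_mirna_filter_join(genes, variant$gene_snp,
                                                    variant$snp_mirna, mirnas)
          dir_ann[[lab]] <- entry
        }
        gwas_fit <- NULL
        if (!is.null(gwas) && length(directions[[dir]]$nonpreserved) > 0) {
          gwas_fit <- gwas_module_enrichment(net$assignment,
                                             directions[[dir]]$nonpreserved, gwas)
        }
        annotation[[dir]] <- list(modules = dir_ann, gwas = gwas_fit)
      }
    }

    stage <- "report"
    metadata <- list(
      seed = config$seed,
      network_type = config$network_type,
      edge_interpretation = config$edge_interpretation,
      powers = list(a = net_a$power, b = net_b$power),
      power_fallback = list(a = net_a$power_fallback, b = net_b$power_fallback),
      r2_target = config$r2_target,
      n_genes = length(shared),
      preservation_n_perm = config$preservation_n_perm,
      hub_n_perm = config$hub_n_perm,
      background = "all genes surviving preprocessing"
    )
    bundle <- list(cohorts = list(a = net_a, b = net_b),
                   directions = directions, annotation = annotation,
                   truth = truth, metadata = metadata)
    if (!is.null(config$output_dir)) write_report_bundle(bundle, config$output_dir)
    bundle
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  bundle
}

#' Write the artifacts of a report bundle to a directory
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(bundle$cohorts)) {
    net <- bundle$cohorts[[ch]]
    jsonlite::write_json(
      list(fit = net$soft_threshold$fit, chosen_power = net$power,
           fallback = net$power_fallback,
           r2_target = net$soft_threshold$r2_target,
           network_type = net$soft_threshold$network_type),
      file.path(dir, sprintf("soft_threshold_%s.json", ch)),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_module_assignment_tsv(net$assignment,
                                file.path(dir, sprintf("modules_%s.tsv", ch)))
  }
  for (dname in names(bundle$directions)) {
    d <- bundle$directions[[dname]]
    utils::write.table(preservation_table(d$preservation),
                       file.path(dir, sprintf("preservation_%s.tsv", dname)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_preservation_json(d$preservation,
                            file.path(dir, sprintf("preservation_%s.json", dname)))
    for (lab in names(d$hubs)) {
      write_hub_table_tsv(d$hubs[[lab]],
                          file.path(dir, sprintf("hubs_%s_%s.tsv", dname, lab)))
    }
  }
  jsonlite::write_json(report_summary(bundle), file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Compact JSON-ready summary of a report bundle
#' @param bundle result of [run_pipeline()].
#' @return a list safe to serialize with jsonlite.
#' @export
report_summary <- function(bundle) {
  list(
    metadata = bundle$metadata,
    modules = lapply(bundle$cohorts, function(net) {
      as.list(table(net$assignment[net$assignment != "unassigned"]))
    }),
    directions = lapply(bundle$directions, function(d) {
      list(
        nonpreserved = as.list(d$nonpreserved),
        preservation = lapply(d$preservation, function(r) {
          list(module = r$module, size = r$size, max_p = r$max_p,
               p_values = as.list(r$p_values), nonpreserved = r$nonpreserved)
        }),
        hubs = lapply(d$hubs, function(tab) as.list(significant_hubs(tab)))
      )
    })
  )
}
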