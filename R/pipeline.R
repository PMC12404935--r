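#' Run the full multi-scale analysis pipeline on synthetic data
#'
#' End-to-end driver: simulates a two-context (T2DM/HTN) case-control
#' expression compendium with planted ground truth, then runs every
#' analysis stage -- preprocessing (QC, quantile normalization,
#' batch adjustment, variance filter), cross-disease moderated
#' differential expression with DEG calls, weighted co-expression
#' network analysis (automatic soft threshold, TOM, modules, eigengenes,
#' module-trait correlation), connectivity rewiring between contexts,
#' PPI hub/community analysis on a simulated STRING-style edge list,
#' regulon-based TF activity per context, gene-set over-representation,
#' the five-layer integrative network with GraphML export, and tissue
#' Z-score profiling -- writing every declared output file under
#' `out_dir`.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [sim_config()]; the defaults emulate the study design
#'   at desk scale.
#' @param seed optional integer overriding `config$seed`.
#' @param var_percentile variance-filter percentile (default 70).
#' @param min_module_size minimum module size for module detection
#'   (default 20, matched to the synthetic module scale; genome-scale
#'   analyses conventionally use 200).
#' @param top_n_rewire genes entering the rewiring analysis (default
#'   100).
#' @param score_min PPI combined-score threshold (default 0.9).
#' @param top_k_hubs hubs reported per PPI network (default 10).
#' @return (invisibly) a list with the main result objects and the
#'   vector of written file paths.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), seed = NULL,
                         var_percentile = 70, min_module_size = 20,
                         top_n_rewire = 100, score_min = 0.9,
                         top_k_hubs = 10) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  p <- function(...) file.path(out_dir, paste0(...))
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  ## -- simulate ------------------------------------------------------
  sim <- simulate_expression(config)
  write_expression_tsv(sim$expr, p("expression.tsv")); emit(p("expression.tsv"))
  write_samples_tsv(sim$samples, p("samples.tsv")); emit(p("samples.tsv"))
  write_ground_truth_json(sim$truth, p("ground_truth.json"))
  emit(p("ground_truth.json"))

  ## -- preprocess ----------------------------------------------------
  qc <- qc_filter(sim$expr)
  .write_tsv(qc$report, p("qc_report.tsv")); emit(p("qc_report.tsv"))
  expr <- quantile_normalize(qc$expr)
  expr <- correct_batch(expr, sim$samples)
  expr_f <- filter_variance(expr, percentile = var_percentile)
  write_expression_tsv(expr_f, p("expression_preprocessed.tsv"))
  emit(p("expression_preprocessed.tsv"))
  outliers <- detect_outlier_samples(expr_f)
  writeLines(outliers, p("outlier_samples.txt")); emit(p("outlier_samples.txt"))

  ## -- differential expression (case vs control) ---------------------
  deg_tab <- call_degs(fit_moderated(expr, sim$samples,
                                     contrast = "case-control"))
  .write_tsv(deg_tab, p("deg_table.tsv")); emit(p("deg_table.tsv"))
  deg_called <- deg_tab[deg_tab$call != "ns", , drop = FALSE]

  ## -- co-expression network ----------------------------------------
  sft <- pick_soft_threshold(expr_f)
  .write_tsv(sft$report, p("soft_threshold.tsv")); emit(p("soft_threshold.tsv"))
  tom <- build_tom(expr_f, sft$power)
  modules <- detect_modules(tom, expr_f,
                            min_module_size = min_module_size)
  .write_tsv(data.frame(gene_id = names(modules),
                        module = unname(modules)),
             p("module_assignments.tsv"))
  emit(p("module_assignments.tsv"))
  me <- module_eigengenes(expr_f, modules)
  .write_tsv(data.frame(module = rownames(me$eigengenes),
                        me$eigengenes, check.names = FALSE),
             p("module_eigengenes.tsv"))
  emit(p("module_eigengenes.tsv"))
  mt <- module_trait_correlation(me$eigengenes, sim$samples)
  .write_tsv(mt, p("module_trait.tsv")); emit(p("module_trait.tsv"))

  ## -- rewiring between contexts ------------------------------------
  in_a <- sim$samples$sample_id[sim$samples$context == "T2DM"]
  in_b <- sim$samples$sample_id[sim$samples$context == "HTN"]
  expr_a <- expr[, in_a, drop = FALSE]
  expr_b <- expr[, in_b, drop = FALSE]
  top <- select_top_diff_genes(expr_a, expr_b, n = top_n_rewire)
  net_a <- correlation_network(expr_a, top)
  net_b <- correlation_network(expr_b, top)
  rew <- rewiring_scores(net_a, net_b)
  .write_tsv(rew, p("rewiring.tsv")); emit(p("rewiring.tsv"))
  de <- differential_edges(net_a, net_b)
  .write_tsv(de, p("differential_edges.tsv"))
  emit(p("differential_edges.tsv"))

  ## -- PPI network on the disease-linked module ----------------------
  dis <- mt[mt$trait == "disease" & mt$module != "ME0", , drop = FALSE]
  top_module <- if (nrow(dis) && any(!is.na(dis$r))) {
    as.integer(sub("^ME", "", dis$module[which.max(abs(dis$r))]))
  } else 0L
  mod_genes <- names(modules)[modules == top_module]
  if (length(mod_genes) < 10L) mod_genes <- rownames(expr_f)
  ppi_edges <- simulate_ppi(mod_genes, community_structure = TRUE,
                            n_blocks = 3, p_within = 0.3,
                            p_between = 0.02, seed = config$seed + 202L)
  write_string_tsv(ppi_edges, p("string_edges.tsv"))
  emit(p("string_edges.tsv"))
  g <- load_string_edges(p("string_edges.tsv"), score_min = score_min)
  cent <- centralities(g)
  .write_tsv(cent, p("ppi_centralities.tsv")); emit(p("ppi_centralities.tsv"))
  hubs <- select_hubs(cent, top_k = top_k_hubs)
  .write_tsv(hubs, p("ppi_hubs.tsv")); emit(p("ppi_hubs.tsv"))
  comm <- detect_communities(g)
  .write_tsv(data.frame(node = names(comm$membership),
                        community = unname(comm$membership)),
             p("ppi_communities.tsv"))
  emit(p("ppi_communities.tsv"))
  jsonlite::write_json(
    list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
         modularity = comm$modularity,
         chosen_power = sft$power, n_modules = max(modules),
         n_degs_called = nrow(deg_called)),
    p("run_summary.json"), auto_unbox = TRUE, digits = NA)
  emit(p("run_summary.json"))

  ## -- TF activity per context --------------------------------------
  reg_all <- simulate_regulons(config)
  write_regulons_tsv(reg_all, p("regulons.tsv")); emit(p("regulons.tsv"))
  reg <- load_regulons(p("regulons.tsv"))
  nes <- activity_nes(expr, reg)
  .write_tsv(data.frame(tf = rownames(nes), nes, check.names = FALSE),
             p("tf_nes.tsv"))
  emit(p("tf_nes.tsv"))
  tf_a <- differential_activity(nes[, in_a, drop = FALSE],
                                sim$samples)
  tf_b <- differential_activity(nes[, in_b, drop = FALSE],
                                sim$samples)
  .write_tsv(tf_a, p("tf_diff_t2dm.tsv")); emit(p("tf_diff_t2dm.tsv"))
  .write_tsv(tf_b, p("tf_diff_htn.tsv")); emit(p("tf_diff_htn.tsv"))

  ## -- enrichment ----------------------------------------------------
  universe <- rownames(expr)
  gmt_sets <- simulate_genesets(universe,
                                enriched_genes = deg_called$gene_id,
                                seed = config$seed + 303L)
  write_gmt(gmt_sets, p("genesets.gmt")); emit(p("genesets.gmt"))
  glist <- if (nrow(deg_called)) deg_called$gene_id else
    head(deg_tab$gene_id[order(deg_tab$p_value)], 20)
  enr <- hypergeom_enrich(glist, universe, read_gmt(p("genesets.gmt")))
  .write_tsv(enr, p("enrichment.tsv")); emit(p("enrichment.tsv"))

  ## -- multilayer network -------------------------------------------
  kme <- if (length(mod_genes) && top_module > 0L) {
    e <- me$eigengenes[paste0("ME", top_module), ]
    setNames(vapply(mod_genes, function(g0) cor(expr_f[g0, ], e),
                    numeric(1)), mod_genes)
  } else numeric(0)
  rew_hit <- rew[rew$class != "stable", , drop = FALSE]
  ml <- build_multilayer(
    deg = setNames(deg_called$log2fc, deg_called$gene_id),
    module = kme,
    rewired = setNames(rew_hit$rewiring_score, rew_hit$gene_id),
    tf_t2dm = setNames(tf_a$mean_diff[tf_a$significant],
                       tf_a$tf[tf_a$significant]),
    tf_htn = setNames(tf_b$mean_diff[tf_b$significant],
                      tf_b$tf[tf_b$significant]))
  export_graphml(ml, p("multilayer.graphml")); emit(p("multilayer.graphml"))

  ## -- tissue profiling ---------------------------------------------
  tissues <- c("pancreas", "liver", "kidney_cortex", "skeletal_muscle",
               "adipose_subcutaneous", "adipose_visceral", "aorta",
               "adrenal_gland")
  genes_tz <- unique(c(deg_called$gene_id,
                       head(rownames(expr_f), 20)))
  specific <- if (nrow(deg_called))
    setNames(rep_len(tissues, min(3L, nrow(deg_called))),
             head(deg_called$gene_id, 3L)) else NULL
  tpm <- simulate_tissue_tpm(genes_tz, tissues, specific = specific,
                             seed = config$seed + 404L)
  write_tpm_tsv(tpm, p("tissue_tpm.tsv")); emit(p("tissue_tpm.tsv"))
  tz <- tissue_zscores(tpm)
  write_tpm_tsv(tz$z, p("tissue_zscores.tsv")); emit(p("tissue_zscores.tsv"))

  invisible(list(sim = sim, expr = expr, expr_filtered = expr_f,
                 deg = deg_tab, soft_threshold = sft, modules = modules,
                 eigengenes = me, module_trait = mt, rewiring = rew,
                 differential_edges = de, ppi_graph = g, hubs = hubs,
                 communities = comm, nes = nes, tf_t2dm = tf_a,
                 tf_htn = tf_b, enrichment = enr, multilayer = ml,
                 tissue_z = tz, files = files))
}
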