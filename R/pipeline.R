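#' Run the full twin-discordance workflow
#'
#' Orchestrates simulate (or load) -> preprocess -> paired differential
#' statistics -> co-twin similarity -> methylation-expression integration ->
#' gene-set enrichment, writing every stage table as TSV plus a JSON
#' manifest of seeds, parameters and per-stage dimensions. Deterministic
#' given the seed.
#'
#' @param config list. Either `simulate = list(...)` arguments for
#'   [simulation_config()], or `inputs = list(beta=, expression=, design=,
#'   probe_map=)` file paths. Optional elements: `cell_type` (defaults to
#'   the first in the design), `fdr` (0.05), `log2_offset` (1),
#'   `quantile_normalize` (`"expr"`, `"none"`), `top_fraction` (0.01),
#'   `disease_top_n` (50), `permutation` (`"off"`, `"exhaustive"`,
#'   `"montecarlo"`), `annotations` (paths `disease_gmt`/`terms_gmt`, or
#'   simulated when absent), `seed`.
#' @param outdir output directory.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_twin_pipeline <- function(config = list(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  fdr <- config$fdr %||% 0.05
  stage <- "configuration"
  res <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("cotwin")),
                   seed = seed, parameters = config[setdiff(names(config),
                                                            c("inputs"))])
  tryCatch({
    ## ---- inputs ----
    if (!is.null(config$inputs)) {
      stage <- "load-inputs"
      inp <- config$inputs
      for (req in c("beta", "expression", "design", "probe_map"))
        if (is.null(inp[[req]]))
          ct_abort("configuration error: inputs$", req, " is missing",
                   class = "cotwin_config_error")
      beta <- read_matrix(inp$beta, "methylation-beta")
      expr <- read_matrix(inp$expression, "expression-intensity")
      design <- read_design(inp$design)
      probe_map <- read_probe_map(inp$probe_map)
      truth <- NULL
    } else {
      stage <- "simulate"
      sim_args <- config$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% seed
      cohort <- simulate_cohort(do.call(simulation_config, sim_args))
      rep_out <- simulate_replicates(cohort$beta, cohort$design,
                                     cohort$config)
      beta <- rep_out$beta; design <- rep_out$design
      expr <- cohort$expression; probe_map <- cohort$probe_map
      truth <- cohort$truth
      res$cohort_config <- cohort$config
    }
    cell_type <- config$cell_type %||% design$cell_type[1]

    stage <- "validate"
    val <- validate_inputs(design, list(methylation = beta,
                                        expression = expr))
    manifest$n_pairs <- as.list(val$n_pairs)
    manifest$excluded_samples <- val$excluded

    ## ---- preprocess ----
    stage <- "preprocess"
    if (!is.null(config$probe_whitelist))
      beta <- filter_probes(beta, readLines(config$probe_whitelist))
    qn <- config$quantile_normalize %||% "expr"
    if (qn %in% c("expr", "both")) expr <- quantile_normalize(expr)
    if (qn %in% c("beta", "both")) beta <- quantile_normalize(beta)
    expr_log <- log2_transform(expr, offset = config$log2_offset %||% 1)
    gene_beta <- aggregate_cpgs_to_gene(beta, probe_map)
    meth_diffs_cpg <- compute_pair_differences(beta, design, cell_type)
    meth_diffs_gene <- compute_pair_differences(gene_beta, design, cell_type)
    expr_diffs <- compute_pair_differences(expr_log, design, cell_type)
    manifest$n_probes <- nrow(beta$values)
    manifest$n_genes <- nrow(gene_beta$values)
    manifest$n_pairs_used <- ncol(meth_diffs_cpg$values)

    ## ---- paired differential statistics ----
    stage <- "diff"
    tt_cpg <- paired_t_test(meth_diffs_cpg)
    adj <- bh_adjust(tt_cpg$p_raw, q = fdr)
    tt_cpg$p_adj <- adj$p_adj; tt_cpg$significant <- adj$significant
    tt_gene <- paired_t_test(meth_diffs_gene)
    adjg <- bh_adjust(tt_gene$p_raw, q = fdr)
    tt_gene$p_adj <- adjg$p_adj; tt_gene$significant <- adjg$significant
    mod_expr <- moderated_t_test(expr_diffs)
    perm_mode <- config$permutation %||% "off"
    if (perm_mode != "off") {
      perm <- signflip_permutation_test(meth_diffs_gene, mode = perm_mode,
                                        B = config$B %||% 10000,
                                        seed = derive_seed(seed, "perm"))
      write.table(perm, file.path(outdir, "permutation_gene.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(tt_cpg, file.path(outdir, "diff_methylation_cpg.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(tt_gene, file.path(outdir, "diff_methylation_gene.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(mod_expr, file.path(outdir, "diff_expression_moderated.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    volc <- volcano_table(tt_gene, "p_raw", fdr = fdr)
    write.table(volc, file.path(outdir, "volcano_methylation_gene.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    volc_e <- volcano_table(mod_expr, "log_odds", fdr = fdr)
    write.table(volc_e, file.path(outdir, "volcano_expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$n_significant_cpg <- sum(tt_cpg$significant, na.rm = TRUE)
    manifest$n_significant_gene <- sum(tt_gene$significant, na.rm = TRUE)

    ## ---- similarity ----
    stage <- "similarity"
    cor_meth <- cotwin_correlation(beta, design, cell_type, "spearman")
    cor_expr <- cotwin_correlation(expr_log, design, cell_type, "pearson")
    write.table(rbind(cbind(assay = "methylation", cor_meth$per_pair),
                      cbind(assay = "expression", cor_expr$per_pair)),
                file.path(outdir, "cotwin_correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$cotwin_correlation <- list(
      methylation = unname(cor_meth$summary["mean"]),
      expression = unname(cor_expr$summary["mean"]))
    if (any(is_replicate(design))) {
      tvb <- technical_vs_biological(beta, design)
      ks <- ks_two_sample(tvb$technical, tvb$biological)
      write.table(data.frame(feature_id = feature_ids(beta),
                             technical = tvb$technical,
                             biological = tvb$biological),
                  file.path(outdir, "technical_vs_biological.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$ks_technical_vs_biological <-
        list(D = ks$D, p_value = ks$p_value)
      res$ks <- ks
    }

    ## ---- integration ----
    stage <- "integration"
    records <- combined_correlation(meth_diffs_gene, expr_diffs)
    ranked <- rank_genes(records)
    top_frac <- config$top_fraction %||% 0.01
    top_genes <- select_top_fraction(ranked, top_frac)
    write.table(format_ranked_table(ranked),
                file.path(outdir, "combined_ranked_full.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(format_ranked_table(ranked, 50),
                file.path(outdir, "combined_ranked_top50.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$n_genes_integrated <- sum(!is.na(ranked$rho))
    manifest$top_fraction_size <- length(top_genes)

    ## ---- enrichment ----
    stage <- "enrichment"
    background <- records$gene_id
    ann <- config$annotations
    if (!is.null(ann$disease_gmt)) {
      disease <- read_gmt(ann$disease_gmt)
      terms <- read_gmt(ann$terms_gmt)
    } else if (!is.null(truth)) {
      sim_ann <- simulate_gene_annotations(background, truth,
                                           seed = derive_seed(seed, "ann"))
      disease <- sim_ann$disease; terms <- sim_ann$terms
      write_gmt(disease, file.path(outdir, "synthetic_disease_set.gmt"))
      write_gmt(terms, file.path(outdir, "synthetic_terms.gmt"))
    } else {
      disease <- NULL; terms <- NULL
    }
    if (!is.null(disease)) {
      disease_top_n <- config$disease_top_n %||% 50
      fis <- fisher_overrepresentation(
        ranked$gene_id[seq_len(min(disease_top_n, nrow(ranked)))],
        disease[[1]]$genes, background)
      enr <- term_enrichment(top_genes, terms, background,
                             ease = isTRUE(config$ease), fdr = fdr)
      write.table(enr, file.path(outdir, "term_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$fisher_disease_set <- list(overlap = fis$overlap,
                                          p_value = fis$p_value)
      res$fisher <- fis
      res$enrichment <- enr
    }

    res <- c(res, list(design = design, truth = truth,
                       diff_cpg = tt_cpg, diff_gene = tt_gene,
                       diff_expression = mod_expr,
                       cotwin_meth = cor_meth, cotwin_expr = cor_expr,
                       ranked = ranked, top_genes = top_genes))
  }, error = function(e) {
    ct_abort("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })

  manifest$stages_completed <- stage
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  res$manifest <- manifest
  invisible(res)
}
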