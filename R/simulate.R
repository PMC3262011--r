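#' Configuration for the synthetic twin cohort generator
#'
#' Bundles and validates all tunable parameters of [simulate_cohort()].
#' Defaults mirror the dimensions of a 27K-methylation / HT-12-expression
#' discordant-twin study: 17 CD4 and 13 CD8 pairs, 11,933 genes shared by
#' both platforms, roughly 2.2 CpG probes per gene (about 26,700 probes),
#' co-twin rank correlation near 0.98, and technical noise half the size of
#' biological co-twin noise.
#'
#' @param n_pairs_per_celltype named integer vector: discordant pairs per
#'   cell type. Pair ids are shared across cell types (the same twins are
#'   assayed in both); cell types beyond the first reuse a prefix of the
#'   first cell type's pairs.
#' @param n_genes number of genes on the (intersected) platform.
#' @param cpgs_per_gene integer range `c(min, max)` of probes per gene. The
#'   default range 1-4 is sampled with decreasing weights so the expected
#'   probe count matches 27K promoter-array density (~2.24 CpGs/gene);
#'   other ranges are sampled uniformly.
#' @param n_planted_genes number of genes given a correlated
#'   methylation-expression discordance signal (in the first cell type).
#' @param latent_effect_meth SD, on the logit-beta scale, of the planted
#'   per-pair methylation discordance signal. Only used when
#'   `target_population_rho` is `NULL`.
#' @param latent_effect_expr SD, in log2 units, of the planted per-pair
#'   expression discordance signal (the logFC signal). Only used when
#'   `target_population_rho` is `NULL`.
#' @param target_population_rho population Spearman correlation between
#'   per-pair delta-beta and logFC for planted genes. When set (the
#'   default, 0.8), the generator sizes each planted gene's methylation and
#'   expression effects from its own noise model so the population
#'   correlation equals this value for every planted gene regardless of
#'   baseline methylation or probe count; set to `NULL` to use the fixed
#'   `latent_effect_*` SDs instead.
#' @param biological_noise_beta average per-sample beta-scale SD of
#'   biological (individual) noise. Noise is heteroscedastic, scaled by
#'   4*beta*(1-beta) and normalized so the probe-average SD equals this value.
#' @param technical_noise_beta average beta-scale SD of technical replicate
#'   noise; must be smaller than `biological_noise_beta`.
#' @param cotwin_correlation_target target mean co-twin Spearman correlation
#'   of the beta columns; the generator calibrates the logit-scale spread to
#'   hit it.
#' @param n_replicated_pairs pairs (first cell type) that receive technical
#'   replicates in [simulate_replicates()].
#' @param n_celltype_specific_features probes given a cell-type-specific
#'   methylation offset (second vs first cell type).
#' @param seed master seed; all stage seeds are derived from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs_per_celltype = c(CD4 = 17, CD8 = 13),
                              n_genes = 11933,
                              cpgs_per_gene = c(1, 4),
                              n_planted_genes = 100,
                              latent_effect_meth = 0.45,
                              latent_effect_expr = 0.45,
                              target_population_rho = 0.8,
                              biological_noise_beta = 0.02,
                              technical_noise_beta = 0.01,
                              cotwin_correlation_target = 0.98,
                              n_replicated_pairs = 7,
                              n_celltype_specific_features = 1300,
                              seed = 1) {
  n_pairs_per_celltype <- unlist(n_pairs_per_celltype) # tolerate JSON lists
  cpgs_per_gene <- as.integer(unlist(cpgs_per_gene))
  cfg <- list(n_pairs_per_celltype = n_pairs_per_celltype,
              n_genes = as.integer(n_genes),
              cpgs_per_gene = as.integer(cpgs_per_gene),
              n_planted_genes = as.integer(n_planted_genes),
              latent_effect_meth = latent_effect_meth,
              latent_effect_expr = latent_effect_expr,
              target_population_rho = target_population_rho,
              biological_noise_beta = biological_noise_beta,
              technical_noise_beta = technical_noise_beta,
              cotwin_correlation_target = cotwin_correlation_target,
              n_replicated_pairs = as.integer(n_replicated_pairs),
              n_celltype_specific_features = as.integer(n_celltype_specific_features),
              seed = as.integer(seed))
  if (is.null(names(cfg$n_pairs_per_celltype)))
    names(cfg$n_pairs_per_celltype) <-
      paste0("CT", seq_along(cfg$n_pairs_per_celltype))
  counts <- c(cfg$n_genes, cfg$n_planted_genes, cfg$n_replicated_pairs,
              cfg$n_celltype_specific_features, cfg$n_pairs_per_celltype)
  if (any(counts < 0))
    ct_abort("configuration error: all counts must be >= 0",
             class = "cotwin_config_error")
  if (length(cfg$cpgs_per_gene) != 2L || cfg$cpgs_per_gene[1] < 1L ||
      cfg$cpgs_per_gene[2] < cfg$cpgs_per_gene[1])
    ct_abort("configuration error: cpgs_per_gene must be a valid (min,max) range",
             class = "cotwin_config_error")
  if (cfg$n_planted_genes > cfg$n_genes)
    ct_abort("configuration error: n_planted_genes (", cfg$n_planted_genes,
             ") exceeds n_genes (", cfg$n_genes, ")",
             class = "cotwin_config_error")
  if (cfg$technical_noise_beta >= cfg$biological_noise_beta &&
      !(cfg$technical_noise_beta == 0 && cfg$biological_noise_beta == 0))
    ct_abort("configuration error: technical_noise_beta must be < biological_noise_beta",
             class = "cotwin_config_error")
  if (cfg$cotwin_correlation_target <= 0 || cfg$cotwin_correlation_target >= 1)
    ct_abort("configuration error: cotwin_correlation_target must lie in (0,1)",
             class = "cotwin_config_error")
  if (!is.null(cfg$target_population_rho) &&
      (cfg$target_population_rho <= 0 || cfg$target_population_rho >= 1))
    ct_abort("configuration error: target_population_rho must lie in (0,1) or be NULL",
             class = "cotwin_config_error")
  if (any(c(cfg$latent_effect_meth, cfg$latent_effect_expr,
            cfg$biological_noise_beta, cfg$technical_noise_beta) < 0))
    ct_abort("configuration error: effect and noise SDs must be >= 0",
             class = "cotwin_config_error")
  structure(cfg, class = "simulation_config")
}

# Internal generative constants (documented in the methods vignette):
# baseline logit-beta mixture (low/intermediate/high methylation), probe
# scatter within a gene, shared per-pair genetic deviation, expression
# baseline and noise, and the cell-type logit offset.
.sim_const <- list(
  mix_weights = c(0.55, 0.15, 0.30),
  mix_means   = c(-2.5, 0.0, 2.2),
  mix_sds     = c(0.8, 1.0, 0.7),
  probe_offset_sd = 0.4,
  pairdev_logit_sd = 0.15,
  expr_baseline_mean = 8, expr_baseline_sd = 1.5,
  expr_pairdev_sd = 0.3,
  expr_noise_sd = 0.15,
  celltype_shift_logit = 1.0,
  cpg_weights_27k = c(0.32, 0.28, 0.24, 0.16)
)

# Heteroscedastic beta-scale noise scale: proportional to 4 b (1-b),
# normalized so the average SD over probes equals the nominal SD.
.h_scale <- function(beta) {
  h <- 4 * beta * (1 - beta)
  m <- mean(h)
  if (m <= 0) return(rep(1, length(beta)))
  h / m
}

# Calibrate the logit spread multiplier so that the measured co-twin
# Spearman correlation matches the target. The relation is monotone
# decreasing on c >= 1 (wider spread pushes probes into the flat tails of
# the inverse logit, where noise scrambles ranks); below the value reached
# at c = 1 the target is unattainable and c = 1 is used with a warning.
.calibrate_spread <- function(logit0, target, noise_sd, n_probe_cal = 8000L) {
  idx <- if (length(logit0) > n_probe_cal)
    sample.int(length(logit0), n_probe_cal) else seq_along(logit0)
  l0 <- logit0[idx]
  z1 <- rnorm(length(l0)); z2 <- rnorm(length(l0))
  f <- function(cc) {
    b <- inv_logit(cc * l0)
    h <- .h_scale(b)
    x <- clip01(b + z1 * noise_sd * h)
    y <- clip01(b + z2 * noise_sd * h)
    cor(x, y, method = "spearman")
  }
  lo <- 1; hi <- 8
  if (noise_sd == 0) return(1)
  if (f(lo) < target) {
    warning("cotwin_correlation_target ", target,
            " not attainable with biological_noise_beta ", noise_sd,
            "; using closest achievable")
    return(lo)
  }
  if (f(hi) > target) return(hi)
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    if (f(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a discordant monozygotic twin cohort with known ground truth
#'
#' Generates methylation beta values (probe level) and expression intensities
#' (gene level) for discordant twin pairs across cell types, together with
#' the sample sheet, probe-to-gene map and truth labels.
#'
#' The generative model: per gene a baseline logit-beta is drawn from a
#' three-component mixture (unmethylated / intermediate / methylated), probes
#' scatter around their gene baseline, and each pair carries a shared
#' deviation per probe implementing MZ genetic identity. Each pair also
#' draws a latent discordance score `z_p`; planted genes add `a * z_p` to
#' the co-twin logit-beta difference and `b * z_p` to the log2-expression
#' difference, with coherent signs, so that per-gene delta-beta and logFC
#' are correlated across pairs. Biological noise is heteroscedastic on the
#' beta scale (SD proportional to `4*beta*(1-beta)`); the logit spread is
#' calibrated so the co-twin Spearman correlation matches the configured
#' target. Betas are clipped to \[0,1\].
#'
#' @param config a [simulation_config()].
#' @return List with elements `beta` ([feature_matrix()], probe level),
#'   `expression` (intensity scale, gene level), `design` ([twin_design()]),
#'   `probe_map` ([probe_gene_map()]), `truth` (planted gene ids, their
#'   expected correlation signs, cell-type-specific probe ids), and the
#'   calibrated `spread_multiplier`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  cst <- .sim_const
  set.seed(derive_seed(config$seed, "cohort"))

  ## gene / probe universe
  G <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(G))
  rng <- config$cpgs_per_gene
  ks <- rng[1]:rng[2]
  w <- if (identical(ks, 1:4)) cst$cpg_weights_27k else rep(1, length(ks))
  ncpg <- if (length(ks) == 1L) rep(ks, G) else sample(ks, G, TRUE, prob = w)
  probe_gene <- rep(gene_ids, ncpg)
  probe_ids <- paste0("cg_", probe_gene, "_",
                      unlist(lapply(ncpg, seq_len), use.names = FALSE))
  P <- length(probe_ids)

  ## baseline methylation: mixture on logit scale + probe scatter
  comp <- sample.int(3L, G, TRUE, prob = cst$mix_weights)
  mu_gene <- rnorm(G, cst$mix_means[comp], cst$mix_sds[comp])
  logit0 <- rep(mu_gene, ncpg) + rnorm(P, 0, cst$probe_offset_sd)

  ## calibrate logit spread toward the co-twin correlation target
  cc <- .calibrate_spread(logit0, config$cotwin_correlation_target,
                          config$biological_noise_beta)
  logit0 <- cc * logit0
  beta0 <- inv_logit(logit0)
  h <- .h_scale(beta0)

  ## sample sheet: pair ids shared across cell types
  cts <- names(config$n_pairs_per_celltype)
  n_max <- max(config$n_pairs_per_celltype)
  pair_ids <- sprintf("P%02d", seq_len(n_max))
  rows <- list()
  for (ct in cts) {
    np <- config$n_pairs_per_celltype[[ct]]
    for (p in pair_ids[seq_len(np)]) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = c(paste0(p, "_U_", ct), paste0(p, "_A_", ct)),
        pair_id = p, status = c("unaffected", "affected"), cell_type = ct,
        stringsAsFactors = FALSE)
    }
  }
  design <- twin_design(do.call(rbind, rows))

  ## truth labels
  planted <- sort(sample(gene_ids, config$n_planted_genes))
  sign_rho <- setNames(sample(c(-1, 1), length(planted), TRUE), planted)
  sign_m <- setNames(sample(c(-1, 1), length(planted), TRUE), planted)
  sign_e <- sign_m * sign_rho
  ct_probes <- if (config$n_celltype_specific_features > 0)
    sort(sample(probe_ids, min(config$n_celltype_specific_features, P)))
  else character()
  ct_shift <- setNames(rep(0, P), probe_ids)
  ct_shift[ct_probes] <- sample(c(-1, 1), length(ct_probes), TRUE) *
    cst$celltype_shift_logit

  ## latent discordance score per pair (signal planted in first cell type).
  ## z is shared by every planted gene, so its realized spread scales all
  ## planted effects jointly; it is standardized to unit sample SD so the
  ## delivered population correlation matches the calibration target
  ## instead of fluctuating with one 17-draw sample SD.
  z_pair <- rnorm(n_max)
  if (n_max > 1 && sd(z_pair) > 0) z_pair <- z_pair / sd(z_pair)
  z_pair <- setNames(z_pair, pair_ids)

  ## shared per-pair genetic deviation (same across cell types and twins)
  pairdev_m <- matrix(rnorm(P * n_max, 0, cst$pairdev_logit_sd), P, n_max,
                      dimnames = list(probe_ids, pair_ids))
  e_gene <- rnorm(G, cst$expr_baseline_mean, cst$expr_baseline_sd)
  pairdev_e <- matrix(rnorm(G * n_max, 0, cst$expr_pairdev_sd), G, n_max,
                      dimnames = list(gene_ids, pair_ids))

  ## per-gene planted effect vectors expanded to probes.
  ## With a target population correlation rho*, both assays get per-assay
  ## signal-to-noise k = sqrt(rho*/(1-rho*)) so that rho* = r_m * r_e with
  ## r_m = r_e = k/sqrt(k^2+1). The methylation effect is sized per gene:
  ## the gene-level deltaBeta noise SD sigma_g follows from the
  ## heteroscedastic noise model, and the logit-scale amplitude is
  ## a_g = 4 k sigma_g / mean(H_probes) since the inverse-logit slope is
  ## H/4 = beta (1 - beta).
  a_probe <- setNames(rep(0, P), probe_ids)
  b_gene <- setNames(rep(0, G), gene_ids)
  if (length(planted)) {
    a_gene_eff <- setNames(rep(0, G), gene_ids)
    rho_star <- config$target_population_rho
    if (!is.null(rho_star)) {
      # rho* is a Spearman target (the statistic the analysis measures);
      # convert to the Pearson correlation of the underlying Gaussian
      # model, then split evenly between the two assays.
      rho_pearson <- 2 * sin(pi * rho_star / 6)
      k <- sqrt(rho_pearson / (1 - rho_pearson))
      gene_of_probe <- factor(probe_gene, levels = gene_ids)
      Hbar <- tapply(h, gene_of_probe, mean)       # normalized noise scale
      Hsq <- tapply(h^2, gene_of_probe, sum)
      sigma_g <- sqrt(2) * config$biological_noise_beta * sqrt(Hsq) / ncpg
      mean_H_raw <- mean(4 * beta0 * (1 - beta0))  # slope_i = h_i*mean_H_raw/4
      a_auto <- pmin(4 * k * sigma_g / pmax(Hbar * mean_H_raw, 1e-6), 2.5)
      a_gene_eff[planted] <- a_auto[planted] * sign_m[planted]
      b_gene[planted] <- k * sqrt(2) * cst$expr_noise_sd * sign_e[planted]
    } else {
      a_gene_eff[planted] <- config$latent_effect_meth * sign_m[planted]
      b_gene[planted] <- config$latent_effect_expr * sign_e[planted]
    }
    a_probe[] <- rep(a_gene_eff, ncpg)
  }

  beta_vals <- matrix(NA_real_, P, nrow(design),
                      dimnames = list(probe_ids, design$sample_id))
  expr_vals <- matrix(NA_real_, G, nrow(design),
                      dimnames = list(gene_ids, design$sample_id))
  first_ct <- cts[1]
  for (i in seq_len(nrow(design))) {
    p <- design$pair_id[i]; ct <- design$cell_type[i]
    half <- if (design$status[i] == "unaffected") 0.5 else -0.5
    signal_on <- (ct == first_ct)
    lg <- logit0 + pairdev_m[, p] +
      (if (ct != first_ct) ct_shift else 0) +
      (if (signal_on) half * a_probe * z_pair[p] else 0)
    b0 <- inv_logit(lg)
    beta_vals[, i] <- clip01(b0 + rnorm(P, 0, config$biological_noise_beta * h))
    le <- e_gene + pairdev_e[, p] +
      (if (signal_on) half * b_gene * z_pair[p] else 0) +
      rnorm(G, 0, cst$expr_noise_sd)
    expr_vals[, i] <- 2^le
  }

  list(beta = feature_matrix(beta_vals, "methylation-beta"),
       expression = feature_matrix(expr_vals, "expression-intensity"),
       design = design,
       probe_map = probe_gene_map(
         data.frame(probe_id = probe_ids, gene_id = probe_gene,
                    stringsAsFactors = FALSE)),
       truth = list(planted_gene_ids = planted,
                    planted_sign = sign_rho,
                    celltype_specific_feature_ids = ct_probes),
       config = config,
       spread_multiplier = cc)
}

#' Append technical replicate samples to a beta matrix
#'
#' Both members of the first `n_replicated_pairs` pairs of the first cell
#' type are re-measured: the replicate column equals the original plus
#' heteroscedastic technical noise (average SD `technical_noise_beta`),
#' clipped to \[0,1\]. The design gains matching rows whose `replicate_of`
#' records provenance.
#'
#' @param beta a beta-valued [feature_matrix()].
#' @param design the cohort [twin_design()].
#' @param config the [simulation_config()] (supplies noise SD, count, seed).
#' @return List with updated `beta` and `design`.
#' @export
simulate_replicates <- function(beta, design, config) {
  stopifnot(inherits(beta, "feature_matrix"))
  set.seed(derive_seed(config$seed, "replicates"))
  first_ct <- design$cell_type[1]
  pairs <- complete_pairs(design, first_ct)
  if (config$n_replicated_pairs > nrow(pairs))
    ct_abort("requested ", config$n_replicated_pairs,
             " replicated pairs but only ", nrow(pairs), " pairs exist")
  sel <- pairs[seq_len(config$n_replicated_pairs), , drop = FALSE]
  samples <- c(rbind(sel$unaffected, sel$affected))
  h <- .h_scale(beta$values)
  vals <- beta$values
  new_rows <- list()
  for (s in samples) {
    rep_id <- paste0(s, "_rep")
    noise <- rnorm(nrow(vals), 0, config$technical_noise_beta) * h[, s]
    newcol <- matrix(clip01(vals[, s] + noise), ncol = 1,
                     dimnames = list(rownames(vals), rep_id))
    vals <- cbind(vals, newcol)
    i <- match(s, design$sample_id)
    new_rows[[rep_id]] <- data.frame(
      sample_id = rep_id, pair_id = design$pair_id[i],
      status = design$status[i], cell_type = design$cell_type[i],
      replicate_of = s, excluded = FALSE, exclude_reason = NA_character_,
      stringsAsFactors = FALSE)
  }
  design2 <- twin_design(rbind(as.data.frame(design),
                               do.call(rbind, new_rows)))
  list(beta = feature_matrix(vals, beta$kind), design = design2)
}

#' Simulate gene-set annotations with recoverable enrichment signal
#'
#' Builds a disease gene set (stand-in for a curated susceptibility list)
#' and a collection of annotation terms. Planted genes are preferentially
#' assigned to the disease set and to a few designated terms so enrichment
#' stages have signal to recover; with `enrichment_bias = 0` both are
#' uniform random draws.
#'
#' @param genes character vector, the gene universe.
#' @param truth truth labels from [simulate_cohort()] (may have zero
#'   planted genes).
#' @param n_terms number of annotation terms.
#' @param disease_set_size size of the disease set.
#' @param enrichment_bias fraction of the disease set (and of each enriched
#'   term) drawn from the planted genes, in \[0,1\].
#' @param n_enriched_terms number of terms that receive planted genes.
#' @param seed integer seed.
#' @return List of two [gene_set_collection()]s: `disease` and `terms`.
#' @export
simulate_gene_annotations <- function(genes, truth = list(planted_gene_ids = character()),
                                      n_terms = 200, disease_set_size = 50,
                                      enrichment_bias = 0.6,
                                      n_enriched_terms = 4, seed = 1) {
  if (!length(genes)) ct_abort("empty gene universe")
  set.seed(derive_seed(seed, "annotations"))
  planted <- intersect(truth$planted_gene_ids %||% character(), genes)
  pick_biased <- function(size) {
    n_pl <- min(round(enrichment_bias * size), length(planted))
    c(if (n_pl) sample(planted, n_pl),
      sample(setdiff(genes, planted), size - n_pl))
  }
  disease <- gene_set_collection(list(
    disease_susceptibility = list(
      description = "synthetic curated disease gene set",
      genes = sort(pick_biased(min(disease_set_size, length(genes)))))))
  sizes <- pmax(5L, pmin(length(genes),
                         round(exp(rnorm(n_terms, log(40), 0.8)))))
  terms <- lapply(seq_len(n_terms), function(i) {
    g <- if (i <= n_enriched_terms && length(planted))
      pick_biased(sizes[i]) else sample(genes, sizes[i])
    list(description = sprintf("synthetic term %d%s", i,
                               if (i <= n_enriched_terms && length(planted))
                                 " (signal)" else ""),
         genes = sort(g))
  })
  names(terms) <- sprintf("TERM:%04d", seq_len(n_terms))
  list(disease = disease, terms = gene_set_collection(terms))
}

#' Write all cohort artifacts to a directory as plain-text files
#'
#' @param cohort result of [simulate_cohort()].
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$beta, file.path(outdir, "beta.tsv"))
  write_matrix(cohort$expression, file.path(outdir, "expression.tsv"))
  write_design(cohort$design, file.path(outdir, "samples.tsv"))
  write_probe_map(cohort$probe_map, file.path(outdir, "probe_map.tsv"))
  truth <- data.frame(
    gene_id = cohort$truth$planted_gene_ids,
    planted_sign = as.integer(cohort$truth$planted_sign),
    stringsAsFactors = FALSE)
  write.table(truth, file.path(outdir, "truth_planted_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cohort$truth$celltype_specific_feature_ids,
             file.path(outdir, "truth_celltype_probes.txt"))
  invisible(outdir)
}
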