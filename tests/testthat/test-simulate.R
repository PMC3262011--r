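test_that("configuration invariants are enforced with informative errors", {
  expect_error(simulation_config(n_planted_genes = 50, n_genes = 10),
               "n_planted_genes")
  expect_error(simulation_config(technical_noise_beta = 0.05,
                                 biological_noise_beta = 0.02),
               "technical_noise_beta")
  expect_error(simulation_config(cotwin_correlation_target = 1.2),
               "cotwin_correlation_target")
  expect_error(simulation_config(n_genes = -1), "counts")
  expect_error(simulation_config(cpgs_per_gene = c(4, 1)), "cpgs_per_gene")
})

test_that("the noiseless degenerate cohort has identical co-twins", {
  cfg <- simulation_config(n_pairs_per_celltype = c(CD4 = 4), n_genes = 50,
                           n_planted_genes = 0, biological_noise_beta = 0,
                           technical_noise_beta = 0,
                           n_replicated_pairs = 0,
                           n_celltype_specific_features = 0, seed = 3)
  ch <- simulate_cohort(cfg)
  pairs <- complete_pairs(ch$design, "CD4")
  for (i in seq_len(nrow(pairs))) {
    expect_identical(ch$beta$values[, pairs$unaffected[i]],
                     ch$beta$values[, pairs$affected[i]])
  }
  d <- compute_pair_differences(ch$beta, ch$design, "CD4")
  expect_true(all(d$values == 0))
})

test_that("cohort dimensions, types and truth labels are consistent", {
  ch <- small_cohort()
  cfg <- ch$config
  expect_identical(ncol(ch$beta$values),
                   as.integer(2 * sum(cfg$n_pairs_per_celltype)))
  expect_identical(nrow(ch$expression$values), cfg$n_genes)
  expect_identical(nrow(ch$beta$values), nrow(ch$probe_map))
  expect_true(all(ch$beta$values >= 0 & ch$beta$values <= 1))
  expect_true(all(ch$expression$values > 0))
  expect_length(ch$truth$planted_gene_ids, cfg$n_planted_genes)
  expect_true(all(ch$truth$planted_gene_ids %in% ch$probe_map$gene_id))
  expect_setequal(names(ch$truth$planted_sign), ch$truth$planted_gene_ids)
  expect_true(all(ch$truth$planted_sign %in% c(-1, 1)))
  expect_true(all(ch$truth$celltype_specific_feature_ids %in%
                    feature_ids(ch$beta)))
})

test_that("simulation is bit-reproducible for a fixed seed", {
  a <- small_cohort(seed = 21)
  b <- small_cohort(seed = 21)
  expect_identical(a$beta$values, b$beta$values)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$truth, b$truth)
  c <- small_cohort(seed = 22)
  expect_false(identical(a$beta$values, c$beta$values))
})

test_that("co-twin Spearman correlation hits the configured target", {
  # moderately sized cohort so the per-pair estimate is stable
  ch <- simulate_cohort(simulation_config(
    n_pairs_per_celltype = c(CD4 = 10), n_genes = 3000,
    n_planted_genes = 0, n_replicated_pairs = 0,
    n_celltype_specific_features = 0, seed = 5))
  cc <- cotwin_correlation(ch$beta, ch$design, "CD4", "spearman")
  expect_lt(abs(mean(cc$per_pair$r) - 0.98), 0.02)

  ch2 <- simulate_cohort(simulation_config(
    n_pairs_per_celltype = c(CD4 = 10), n_genes = 3000,
    n_planted_genes = 0, n_replicated_pairs = 0,
    n_celltype_specific_features = 0,
    cotwin_correlation_target = 0.96, seed = 5))
  cc2 <- cotwin_correlation(ch2$beta, ch2$design, "CD4", "spearman")
  expect_lt(abs(mean(cc2$per_pair$r) - 0.96), 0.02)
})

test_that("replicates: zero technical noise copies columns; provenance kept", {
  ch <- small_cohort()
  cfg0 <- ch$config
  cfg0$technical_noise_beta <- 0
  out <- simulate_replicates(ch$beta, ch$design, cfg0)
  reps <- out$design[!is.na(out$design$replicate_of), ]
  expect_identical(nrow(reps), 2L * cfg0$n_replicated_pairs)
  for (i in seq_len(nrow(reps)))
    expect_identical(unname(out$beta$values[, reps$sample_id[i]]),
                     unname(out$beta$values[, reps$replicate_of[i]]))
  # replicates never enter pairing
  expect_identical(nrow(complete_pairs(out$design, "CD4")),
                   nrow(complete_pairs(ch$design, "CD4")))
})

test_that("requesting more replicates than pairs fails", {
  ch <- small_cohort()
  cfg <- ch$config
  cfg$n_replicated_pairs <- 99L
  expect_error(simulate_replicates(ch$beta, ch$design, cfg), "99")
})

test_that("self-self differences are smaller than co-twin differences", {
  ch <- simulate_cohort(simulation_config(
    n_pairs_per_celltype = c(CD4 = 13), n_genes = 2000,
    n_planted_genes = 0, n_replicated_pairs = 7,
    n_celltype_specific_features = 0, seed = 9))
  out <- simulate_replicates(ch$beta, ch$design, ch$config)
  tvb <- technical_vs_biological(out$beta, out$design)
  expect_lt(median(tvb$technical), median(tvb$biological))
  ks <- ks_two_sample(tvb$technical, tvb$biological)
  expect_lt(ks$p_value, 1e-6)
})

test_that("annotations: bias places planted genes; degenerate cases error", {
  ch <- small_cohort()
  genes <- unique(ch$probe_map$gene_id)
  ann <- simulate_gene_annotations(genes, ch$truth, seed = 4)
  expect_s3_class(ann$disease, "gene_set_collection")
  expect_gt(length(intersect(ann$disease[[1]]$genes,
                             ch$truth$planted_gene_ids)), 0)
  expect_error(simulate_gene_annotations(character(), ch$truth), "empty")

  # a term containing exactly the planted genes must rank first
  terms <- gene_set_collection(c(
    list(perfect = list(description = "exactly the planted genes",
                        genes = ch$truth$planted_gene_ids)),
    setNames(lapply(1:5, function(i) {
      set.seed(100 + i)
      list(description = "random", genes = sample(genes, 30))
    }), paste0("rand", 1:5))))
  enr <- term_enrichment(ch$truth$planted_gene_ids, terms, genes)
  expect_identical(enr$term_id[1], "perfect")
})

test_that("cohort artifacts serialize to a directory of plain text files", {
  ch <- small_cohort(n_genes = 60, n_planted = 5)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  expect_true(all(file.exists(file.path(dir,
    c("beta.tsv", "expression.tsv", "samples.tsv", "probe_map.tsv",
      "truth_planted_genes.tsv")))))
  back <- read_matrix(file.path(dir, "beta.tsv"), "methylation-beta")
  expect_equal(back$values, ch$beta$values, tolerance = 1e-12)
})
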