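test_that("filter_probes keeps whitelist rows in order", {
  m <- fm(matrix(runif(10), 5, 2))
  expect_identical(filter_probes(m, feature_ids(m))$values, m$values)
  f <- filter_probes(m, c("f002", "f004"))
  expect_identical(feature_ids(f), c("f002", "f004"))
  expect_error(filter_probes(m, c("nope")), "no probes")
  expect_error(filter_probes(m, character()), "empty")
})

test_that("quantile normalization matches the hand-computed reference", {
  m <- fm(matrix(c(1, 3, 2, 4), 2), kind = "expression-intensity")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values), matrix(c(1.5, 3.5, 1.5, 3.5), 2))

  # identical columns are unchanged
  m2 <- fm(matrix(c(5, 1, 7, 5, 1, 7), 3), kind = "expression-intensity")
  expect_equal(quantile_normalize(m2)$values, m2$values)

  expect_error(quantile_normalize(fm(matrix(1:3, 3, 1),
                                     kind = "expression-intensity")),
               ">= 2 samples")
})

test_that("quantile normalization is idempotent, equivariant, tie-correct", {
  set.seed(8)
  m <- fm(matrix(rexp(60, 1 / 50) + 1, 12, 5), kind = "expression-intensity")
  q1 <- quantile_normalize(m)
  q2 <- quantile_normalize(q1)
  expect_equal(q1$values, q2$values, tolerance = 1e-9)

  # permuting columns permutes the output identically
  perm <- c(3, 1, 5, 2, 4)
  qp <- quantile_normalize(
    feature_matrix(m$values[, perm], "expression-intensity"))
  expect_equal(qp$values, q1$values[, perm])

  # ties share the mean of the reference values they span
  mt <- fm(matrix(c(1, 1, 5, 2, 3, 4), 3), kind = "expression-intensity")
  qt_ <- quantile_normalize(mt)
  ref <- rowMeans(apply(mt$values, 2, sort))
  expect_equal(unname(qt_$values[1:2, 1]),
               rep(mean(ref[1:2]), 2))
})

test_that("log2 transform obeys its closed forms", {
  m <- fm(matrix(c(1, 0, 2^5 - 1, 2^10 - 1), 2),
          kind = "expression-intensity")
  lt <- log2_transform(m, offset = 1)
  expect_equal(unname(lt$values), matrix(c(1, 0, 5, 10), 2))
  expect_identical(lt$kind, "expression-log2")
  expect_error(log2_transform(fm(matrix(c(0.5, 1, 2, 3), 2),
                                 kind = "expression-log2"), offset = -1),
               "non-positive")
})

test_that("gene aggregation is the unweighted probe mean", {
  vals <- matrix(c(0.2, 0.4, 0.9, 0.25, 0.45, 0.95), 3,
                 dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2")))
  map <- probe_gene_map(data.frame(
    probe_id = c("cg1", "cg2", "cg3", "cg_absent"),
    gene_id = c("GA", "GA", "GB", "GC")))
  g <- aggregate_cpgs_to_gene(feature_matrix(vals, "methylation-beta"), map)
  expect_identical(g$kind, "gene-beta")
  expect_equal(g$values["GA", ], c(s1 = 0.3, s2 = 0.35))
  expect_equal(g$values["GB", ], c(s1 = 0.9, s2 = 0.95))  # single probe passes through
  expect_false("GC" %in% feature_ids(g))                  # no probes present
})

test_that("pair differences have the fixed unaffected-minus-affected orientation", {
  d <- tiny_design(2)
  vals <- matrix(c(0.6, 0.3, 0.4, 0.3, 0.5, 0.8, 0.5, 0.8), 2,
                 dimnames = list(c("f1", "f2"),
                                 c("P01_U", "P01_A", "P02_U", "P02_A")))
  pd <- compute_pair_differences(feature_matrix(vals, "gene-beta"), d, "CD4")
  expect_identical(pd$kind, "deltaBeta")
  expect_equal(pd$values["f1", "P01"], 0.2)
  expect_equal(pd$values["f1", "P02"], 0)
  expect_equal(pd$values["f2", "P01"], 0)  # identical co-twins -> zero column

  lvals <- matrix(c(5, 3, 6, 3, 4, 1, 4, 1), 2,
                  dimnames = list(c("g1", "g2"),
                                  c("P01_U", "P01_A", "P02_U", "P02_A")))
  le <- compute_pair_differences(feature_matrix(lvals, "expression-log2"),
                                 d, "CD4")
  expect_identical(le$kind, "logFC")
  expect_equal(le$values["g1", "P01"], -1)  # lower in the unaffected twin

  expect_error(compute_pair_differences(
    feature_matrix(lvals, "expression-log2"), d, "CD19"), "no complete pair")
})

test_that("swapping every status label negates all differences", {
  ch <- small_cohort(n_genes = 80, n_planted = 5)
  pd <- compute_pair_differences(ch$beta, ch$design, "CD4")
  flipped <- as.data.frame(ch$design)
  flipped$status <- ifelse(flipped$status == "affected", "unaffected",
                           "affected")
  pd2 <- compute_pair_differences(ch$beta, twin_design(flipped), "CD4")
  expect_equal(pd2$values, -pd$values)
})

test_that("aggregation and differencing commute", {
  ch <- small_cohort(n_genes = 60, n_planted = 5)
  g_then_d <- compute_pair_differences(
    aggregate_cpgs_to_gene(ch$beta, ch$probe_map), ch$design, "CD4")
  d_then_g <- compute_pair_differences(ch$beta, ch$design, "CD4")
  agg <- rowsum(d_then_g$values, ch$probe_map$gene_id[
    match(rownames(d_then_g$values), ch$probe_map$probe_id)]) /
    as.vector(table(ch$probe_map$gene_id)[sort(unique(ch$probe_map$gene_id))])
  expect_equal(g_then_d$values, agg[rownames(g_then_d$values), ],
               tolerance = 1e-12)
})

test_that("cell-type contrast pairs individuals across cell types", {
  ch <- small_cohort()
  cd <- compute_celltype_differences(ch$beta, ch$design, c("CD4", "CD8"),
                                     status = "unaffected")
  # only pairs assayed in both cell types contribute
  expect_identical(ncol(cd$values),
                   min(as.integer(ch$config$n_pairs_per_celltype)))
  # planted cell-type probes separate from background
  tt <- paired_t_test(cd)
  adj <- bh_adjust(tt$p_raw)
  hits <- tt$feature_id[which(adj$significant)]
  expect_gt(length(intersect(hits, ch$truth$celltype_specific_feature_ids)),
            0L)
})
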