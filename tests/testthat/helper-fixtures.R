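# Shared fixture builders; everything is generated in code.

options(cotwin.verbose = FALSE)

# Minimal complete design: n_pairs discordant pairs in one cell type.
tiny_design <- function(n_pairs, cell_type = "CD4") {
  pid <- sprintf("P%02d", seq_len(n_pairs))
  twin_design(data.frame(
    sample_id = c(paste0(pid, "_U"), paste0(pid, "_A")),
    pair_id = rep(pid, 2),
    status = rep(c("unaffected", "affected"), each = n_pairs),
    cell_type = cell_type,
    stringsAsFactors = FALSE))
}

# feature_matrix from a plain matrix, auto-naming dims when absent.
fm <- function(values, kind = "methylation-beta") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  feature_matrix(values, kind)
}

# paired_differences from a plain matrix of per-pair differences.
pdiff <- function(values, kind = "logFC") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("P%02d", seq_len(ncol(values)))
  paired_differences(values, kind)
}

# A small cohort used by several suites (kept small to stay fast).
small_cohort <- function(seed = 11, n_pairs = c(CD4 = 8, CD8 = 6),
                         n_genes = 400, n_planted = 20, ...) {
  simulate_cohort(simulation_config(
    n_pairs_per_celltype = n_pairs, n_genes = n_genes,
    n_planted_genes = n_planted, n_replicated_pairs = 4,
    n_celltype_specific_features = 40, seed = seed, ...))
}

# Literal brute-force sign-flip oracle: recompute t for every sign vector.
brute_force_signflip <- function(d) {
  n <- length(d)
  tstat <- function(x) mean(x) / (sd(x) / sqrt(n))
  t_obs <- abs(tstat(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t_all <- apply(signs, 1, function(s) abs(tstat(s * d)))
  mean(t_all >= t_obs - 1e-10)
}

# Quadratic-time BH reference: adj_i = min over j with p_j >= p_i of m*p_j/rank_j.
bh_quadratic <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j)
      if (r[j] >= r[i]) m * p[j] / r[j] else Inf, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# Hypergeometric upper tail by literal summation over all admissible tables.
hyper_tail_enum <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(vapply(ks, function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
}
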