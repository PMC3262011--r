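# Average-rank Spearman correlation of two vectors.
.spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

# Exact two-sided permutation p for Spearman's rho: enumerate all n!
# orderings of one vector and count |rho_perm| >= |rho_obs|.
.spearman_exact_p <- function(x, y, max_n = 9L) {
  n <- length(x)
  if (n > max_n) {
    # enumeration infeasible; only the |rho| = 1 case is needed here,
    # where exactly the identity and reversal permutations achieve it
    # (tie-free by construction when |rho| = 1)
    return(2 / factorial(n))
  }
  rho_obs <- abs(.spearman(x, y))
  perms <- .permutations(n)
  ry <- rank(y, ties.method = "average")
  rx <- rank(x, ties.method = "average")
  cnt <- 0L
  for (i in seq_len(nrow(perms))) {
    r <- cor(rx, ry[perms[i, ]])
    if (abs(r) >= rho_obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / nrow(perms)
}

# All permutations of 1..n as a matrix (n! rows).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Two-sided p for Spearman's rho via the t-approximation,
# t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df.
.spearman_t_p <- function(rho, n) {
  if (is.na(rho) || n < 3) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tt), df = n - 2)
}

#' Correlate co-twin methylation differences with expression fold changes
#'
#' The integrative step: per gene, Spearman's rho between the per-pair
#' gene-level delta-beta vector and the per-pair log fold change vector,
#' across the pairs common to both assays. Genes are restricted to the
#' intersection of the two difference sets (the platform overlap). The
#' two-sided p-value uses the t-approximation by default; exact permutation
#' enumeration is available for small n and is always used when |rho| = 1
#' (where the t-approximation degenerates to 0).
#'
#' @param meth_diffs gene-level `deltaBeta` [paired_differences()].
#' @param expr_diffs `logFC` [paired_differences()].
#' @param p_method `"tapprox"` or `"exact"` (exact enumeration requires
#'   `n <= max_exact_n`).
#' @param min_pairs genes with fewer common pairs are skipped (logged).
#' @param max_exact_n largest n for full permutation enumeration.
#' @return Data frame of gene correlation records: `gene_id`, `rho`,
#'   `p_value`, `mean_deltaBeta`, `mean_logFC`, `n_pairs_used`.
#' @export
combined_correlation <- function(meth_diffs, expr_diffs,
                                 p_method = c("tapprox", "exact"),
                                 min_pairs = 3L, max_exact_n = 9L) {
  stopifnot(inherits(meth_diffs, "paired_differences"),
            inherits(expr_diffs, "paired_differences"))
  p_method <- match.arg(p_method)
  genes <- intersect(rownames(meth_diffs$values), rownames(expr_diffs$values))
  if (!length(genes)) ct_abort("no genes shared between the two assays")
  pairs <- intersect(colnames(meth_diffs$values), colnames(expr_diffs$values))
  if (length(pairs) < min_pairs)
    ct_abort("fewer than ", min_pairs, " pairs shared between assays")
  M <- meth_diffs$values[genes, pairs, drop = FALSE]
  E <- expr_diffs$values[genes, pairs, drop = FALSE]
  n <- length(pairs)
  skipped <- 0L
  rho <- numeric(length(genes))
  pval <- numeric(length(genes))
  npairs <- integer(length(genes))
  for (i in seq_along(genes)) {
    mi <- M[i, ]; ei <- E[i, ]
    ok <- !is.na(mi) & !is.na(ei)
    ni <- sum(ok)
    npairs[i] <- ni
    if (ni < min_pairs) {
      rho[i] <- NA_real_; pval[i] <- NA_real_
      skipped <- skipped + 1L
      next
    }
    r <- .spearman(mi[ok], ei[ok])
    rho[i] <- r
    pval[i] <- if (is.na(r)) {
      NA_real_
    } else if (p_method == "exact" || abs(r) >= 1 - 1e-12) {
      .spearman_exact_p(mi[ok], ei[ok],
                        max_n = if (abs(r) >= 1 - 1e-12) n else max_exact_n)
    } else {
      .spearman_t_p(r, ni)
    }
  }
  if (skipped) ct_log("combined_correlation: ", skipped,
                      " gene(s) skipped (fewer than ", min_pairs,
                      " usable pairs)")
  data.frame(gene_id = genes, rho = rho, p_value = pval,
             mean_deltaBeta = rowMeans(M, na.rm = TRUE),
             mean_logFC = rowMeans(E, na.rm = TRUE),
             n_pairs_used = npairs, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rank genes by significance of the methylation-expression correlation
#'
#' Ascending p-value; ties broken by descending |rho|, then gene id, so the
#' order is fully deterministic. NA records sink to the bottom.
#'
#' @param records data frame from [combined_correlation()].
#' @return The same records, ordered, with a `rank` column prepended.
#' @export
rank_genes <- function(records) {
  if (!nrow(records)) ct_abort("empty records")
  o <- order(records$p_value, -abs(records$rho), records$gene_id,
             na.last = TRUE)
  out <- records[o, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Select the top fraction of ranked genes
#'
#' The first `ceiling(fraction * G)` genes of the ranked list — e.g. the
#' top 1% of 11,933 genes is 120 genes.
#'
#' @param ranked output of [rank_genes()].
#' @param fraction fraction in (0, 1\].
#' @return Character vector of gene ids.
#' @export
select_top_fraction <- function(ranked, fraction = 0.01) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    ct_abort("fraction must lie in (0, 1]")
  k <- ceiling(fraction * nrow(ranked))
  ranked$gene_id[seq_len(k)]
}

#' Round a ranked table for reporting
#'
#' Mirrors the conventional presentation: rho to 2 decimals, p to 5,
#' effects to 4.
#'
#' @param ranked output of [rank_genes()].
#' @param top number of rows to keep (default all).
#' @return Data frame ready for TSV export.
#' @export
format_ranked_table <- function(ranked, top = nrow(ranked)) {
  out <- head(ranked, top)
  out$rho <- round(out$rho, 2)
  out$p_value <- round(out$p_value, 5)
  out$mean_deltaBeta <- round(out$mean_deltaBeta, 4)
  out$mean_logFC <- round(out$mean_logFC, 4)
  out
}
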