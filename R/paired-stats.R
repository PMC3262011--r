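#' Per-feature paired t-tests on co-twin differences
#'
#' For each feature, `t = mean(d) / (sd(d)/sqrt(n))` on the per-pair
#' differences with `df = n - 1` and a two-sided p-value from Student's t.
#' Features whose differences have zero variance (or any NA) get `p = NA`
#' and are excluded from downstream FDR adjustment.
#'
#' @param diffs a [paired_differences()] object.
#' @return Data frame with columns `feature_id`, `mean_diff`, `t`, `df`,
#'   `p_raw`.
#' @export
paired_t_test <- function(diffs) {
  stopifnot(inherits(diffs, "paired_differences"))
  d <- diffs$values
  n <- ncol(d)
  if (n < 2L) ct_abort("paired t-test needs >= 2 pairs")
  m <- rowMeans(d)
  s2 <- rowSums((d - m)^2) / (n - 1)
  tt <- ifelse(s2 > 0, m / sqrt(s2 / n), NA_real_)
  tt[apply(d, 1, anyNA)] <- NA_real_
  p <- 2 * pt(-abs(tt), df = n - 1)
  nbad <- sum(is.na(tt))
  if (nbad) ct_log("paired_t_test: ", nbad,
                   " zero-variance/NA feature(s) set to p = NA")
  data.frame(feature_id = rownames(d), mean_diff = m, t = tt,
             df = n - 1L, p_raw = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `adj_i = min over j >= rank(i) of m * p_(j) / j`, capped at 1. NA
#' p-values are carried through as NA and do not count toward `m`.
#'
#' @param p numeric vector of raw p-values in \[0,1\] (NAs allowed).
#' @param q FDR threshold used for the significance flags.
#' @return Data frame with `p_raw`, `p_adj`, `significant`
#'   (`p_adj < q`).
#' @export
bh_adjust <- function(p, q = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    ct_abort("p-values must lie in [0,1]")
  adj <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m > 0) {
    pv <- p[ok]
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    adj[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  }
  data.frame(p_raw = p, p_adj = adj,
             significant = !is.na(adj) & adj < q)
}

# All 2^n sign vectors as a (+/-1) matrix; columns are pairs.
.sign_matrix <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(m) <- NULL
  m
}

#' Sign-flip permutation test for paired differences
#'
#' The exact null for a paired design: each pair's difference is multiplied
#' by every sign vector in `{-1,+1}^n` ("permutations of the affection
#' status in all possible combinations"). Because the sum of squares is
#' sign-invariant, `|t|` exceeds the observed `|t|` exactly when the
#' permuted `|sum(s_i d_i)|` exceeds the observed `|sum(d_i)|`, which is how
#' the enumeration is carried out. The observed arrangement is included in
#' the count, so `p >= 2/2^n` always. Monte Carlo mode draws `B` random
#' sign vectors and uses `p = (1 + #exceed) / (1 + B)`.
#'
#' @param diffs a [paired_differences()] object.
#' @param mode `"exhaustive"` (all `2^n` arrangements) or `"montecarlo"`.
#' @param B Monte Carlo draws.
#' @param seed seed for Monte Carlo mode.
#' @param max_exhaustive_pairs refuse exhaustive enumeration above this
#'   many pairs (default 20, i.e. 2^20 arrangements).
#' @return Data frame `feature_id`, `t`, `p_perm`; the number of
#'   arrangements is attached as attribute `n_arrangements`.
#' @export
signflip_permutation_test <- function(diffs,
                                      mode = c("exhaustive", "montecarlo"),
                                      B = 10000, seed = 1,
                                      max_exhaustive_pairs = 20L) {
  stopifnot(inherits(diffs, "paired_differences"))
  mode <- match.arg(mode)
  d <- diffs$values
  n <- ncol(d)
  if (n < 2L) ct_abort("sign-flip test needs >= 2 pairs")
  tt <- paired_t_test(diffs)$t
  obs <- abs(rowSums(d))
  tol <- 1e-12 * pmax(obs, 1)
  if (mode == "exhaustive") {
    if (n > max_exhaustive_pairs)
      ct_abort("exhaustive enumeration over 2^", n, " arrangements exceeds ",
               "the cap of 2^", max_exhaustive_pairs,
               "; use mode = 'montecarlo'")
    S <- .sign_matrix(n)
    n_arr <- nrow(S)
    p <- numeric(nrow(d))
    block <- max(1L, floor(2^22 / n_arr))
    for (st in seq(1L, nrow(d), by = block)) {
      en <- min(st + block - 1L, nrow(d))
      sums <- abs(S %*% t(d[st:en, , drop = FALSE]))
      p[st:en] <- colSums(sums >= rep(obs[st:en] - tol[st:en],
                                      each = n_arr)) / n_arr
    }
  } else {
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), B * n, TRUE), B, n)
    n_arr <- B
    exceed <- numeric(nrow(d))
    block <- max(1L, floor(2^22 / B))
    for (st in seq(1L, nrow(d), by = block)) {
      en <- min(st + block - 1L, nrow(d))
      sums <- abs(S %*% t(d[st:en, , drop = FALSE]))
      exceed[st:en] <- colSums(sums >= rep(obs[st:en] - tol[st:en], each = B))
    }
    p <- (1 + exceed) / (1 + B)
  }
  structure(data.frame(feature_id = rownames(d), t = tt, p_perm = p,
                       row.names = NULL, stringsAsFactors = FALSE),
            n_arrangements = if (mode == "exhaustive") 2^n else B)
}

#' Volcano-style table export
#'
#' Tabulates per-feature effect size against a significance axis:
#' `-log10(p_adj)`, `-log10(p_raw)` or the moderated-t log-odds. The value
#' of the significance axis at the FDR threshold is attached as attribute
#' `threshold_line` (for `-log10` axes).
#'
#' @param results data frame from [paired_t_test()] (+ [bh_adjust()]) or
#'   [moderated_t_test()].
#' @param significance_axis one of `"p_adj"`, `"p_raw"`, `"log_odds"`.
#' @param fdr FDR threshold drawn as the reference line.
#' @return Data frame `feature_id`, `effect`, `y`.
#' @export
volcano_table <- function(results, significance_axis = c("p_adj", "p_raw",
                                                         "log_odds"),
                          fdr = 0.05) {
  significance_axis <- match.arg(significance_axis)
  if (!nrow(results)) ct_abort("empty results")
  y <- switch(significance_axis,
              p_adj = -log10(results$p_adj),
              p_raw = -log10(results$p_raw),
              log_odds = results$log_odds)
  out <- data.frame(feature_id = results$feature_id,
                    effect = results$mean_diff, y = y,
                    stringsAsFactors = FALSE)
  thr <- if (significance_axis %in% c("p_adj", "p_raw")) -log10(fdr) else NA_real_
  structure(out, significance_axis = significance_axis,
            threshold_line = thr)
}
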