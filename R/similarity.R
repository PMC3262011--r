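#' Per-pair co-twin correlation
#'
#' Correlates the full feature vector between the two members of each
#' complete pair — Spearman for methylation (the field's convention for
#' bounded, non-normal beta values) and Pearson for log-scale expression.
#'
#' @param x a [feature_matrix()].
#' @param design the [twin_design()].
#' @param cell_type cell type whose pairs are used.
#' @param method `"spearman"` or `"pearson"`.
#' @return List with `per_pair` (data frame `pair_id`, `r`) and `summary`
#'   (mean/min/max, rounded to 2 decimals for reporting).
#' @export
cotwin_correlation <- function(x, design, cell_type,
                               method = c("spearman", "pearson")) {
  stopifnot(inherits(x, "feature_matrix"))
  method <- match.arg(method)
  if (nrow(x$values) < 3L) ct_abort("need >= 3 features for correlation")
  pairs <- complete_pairs(design, cell_type)
  sid <- sample_ids(x)
  pairs <- pairs[pairs$unaffected %in% sid & pairs$affected %in% sid, ,
                 drop = FALSE]
  if (!nrow(pairs)) ct_abort("no complete pairs in matrix for ", cell_type)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    u <- x$values[, pairs$unaffected[i]]
    a <- x$values[, pairs$affected[i]]
    if (sd(u) == 0 || sd(a) == 0) {
      warning("constant column for pair ", pairs$pair_id[i], "; r = NA")
      return(NA_real_)
    }
    cor(u, a, method = method)
  }, numeric(1))
  per_pair <- data.frame(pair_id = pairs$pair_id, r = r,
                         stringsAsFactors = FALSE)
  list(per_pair = per_pair,
       summary = round(c(mean = mean(r, na.rm = TRUE),
                         min = min(r, na.rm = TRUE),
                         max = max(r, na.rm = TRUE)), 2),
       method = method, n_pairs = nrow(pairs))
}

#' Technical versus biological per-CpG differences
#'
#' Technical differences are |sample - its technical replicate| per CpG,
#' averaged over replicated samples; biological differences are
#' |unaffected - affected| per CpG, averaged over complete pairs. Both are
#' returned in aligned feature order so their distributions can be
#' contrasted (e.g. with [ks_two_sample()]).
#'
#' @param beta a beta-valued [feature_matrix()] containing replicate columns.
#' @param design the [twin_design()] with `replicate_of` set for replicates.
#' @param cell_type optional cell type restriction.
#' @return List with numeric vectors `technical` and `biological` (one value
#'   per CpG) and the counts used.
#' @export
technical_vs_biological <- function(beta, design, cell_type = NULL) {
  stopifnot(inherits(beta, "feature_matrix"))
  reps <- design[is_replicate(design) & !design$excluded, , drop = FALSE]
  if (!is.null(cell_type)) reps <- reps[reps$cell_type %in% cell_type, ,
                                        drop = FALSE]
  if (!nrow(reps)) ct_abort("no technical replicates in the design")
  sid <- sample_ids(beta)
  reps <- reps[reps$sample_id %in% sid & reps$replicate_of %in% sid, ,
               drop = FALSE]
  if (!nrow(reps)) ct_abort("replicate samples absent from the matrix")
  tech <- abs(beta$values[, reps$sample_id, drop = FALSE] -
                beta$values[, reps$replicate_of, drop = FALSE])
  cts <- if (is.null(cell_type)) unique(design$cell_type) else cell_type
  bio_cols <- list()
  for (ct in cts) {
    pairs <- complete_pairs(design, ct)
    pairs <- pairs[pairs$unaffected %in% sid & pairs$affected %in% sid, ,
                   drop = FALSE]
    if (nrow(pairs))
      bio_cols[[ct]] <- abs(beta$values[, pairs$unaffected, drop = FALSE] -
                              beta$values[, pairs$affected, drop = FALSE])
  }
  if (!length(bio_cols)) ct_abort("no complete pairs for biological contrast")
  bio <- do.call(cbind, bio_cols)
  list(technical = rowMeans(tech), biological = rowMeans(bio),
       n_replicates = nrow(reps), n_pair_columns = ncol(bio))
}

# Asymptotic two-sided Kolmogorov distribution tail, Q(lambda) =
# 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2).
.kolmogorov_tail <- function(lambda) {
  if (lambda < 0.05) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

# Exact two-sided two-sample KS p by lattice-path counting (tie-free
# samples): D is a multiple of 1/(n*m), so admissibility of a lattice
# point (i, j) is the integer condition |i*m - j*n| < round(D*n*m).
# P(D >= d) = 1 - (#paths with all points admissible) / choose(n+m, n).
.ks_exact_p <- function(n, m, d) {
  K <- round(d * n * m)
  u <- numeric(m + 1) # u[j+1] = admissible paths reaching (i, j)
  u[1] <- 1
  for (j in seq_len(m)) u[j + 1] <- if (j * n >= K) 0 else u[j]
  for (i in seq_len(n)) {
    u[1] <- if (i * m >= K) 0 else u[1]
    for (j in seq_len(m)) {
      u[j + 1] <- if (abs(i * m - j * n) >= K) 0 else u[j + 1] + u[j]
    }
  }
  p <- 1 - u[m + 1] / choose(n + m, n)
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |F_x - F_y|` over the pooled sample, with a two-sided p-value
#' from the asymptotic Kolmogorov distribution at the effective sample size
#' `n*m/(n+m)` (the standard choice for the array-scale sample sizes this
#' pipeline produces). For small tie-free samples (both below `exact_below`)
#' the exact lattice-path p-value is used instead.
#'
#' @param x,y numeric samples.
#' @param exact_below use the exact method when `max(n, m) < exact_below`
#'   and there are no ties.
#' @return List with `D`, `p_value`, `method`.
#' @export
ks_two_sample <- function(x, y, exact_below = 50) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) ct_abort("empty sample in KS test")
  n <- length(x); m <- length(y)
  pooled <- sort(unique(c(x, y)))
  fx <- vapply(pooled, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pooled, function(t) mean(y <= t), numeric(1))
  D <- max(abs(fx - fy))
  ties <- anyDuplicated(c(x, y)) > 0
  if (max(n, m) < exact_below && !ties) {
    p <- .ks_exact_p(n, m, D)
    method <- "exact"
  } else {
    neff <- n * m / (n + m)
    p <- .kolmogorov_tail(sqrt(neff) * D)
    method <- "asymptotic"
  }
  list(D = D, p_value = p, method = method, n = n, m = m)
}
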