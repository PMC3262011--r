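# Empirical-Bayes moderated t for paired differences.
#
# The per-feature variances s_g^2 (df d = n-1 each) are modeled as scaled
# F-draws around a prior s0^2 with d0 prior df. Hyperparameters are
# estimated by moment matching on z_g = log(s_g^2):
#   E[z] = log(s0^2) + digamma(d/2) - log(d/2) - (digamma(d0/2) - log(d0/2))
#   Var[z] = trigamma(d/2) + trigamma(d0/2)
# so d0 solves trigamma(d0/2) = var(e) - trigamma(d/2) with
# e = z - digamma(d/2) + log(d/2); if the right side is <= 0 the
# variances are less dispersed than pure sampling noise and d0 = Inf.

# Inverse of trigamma by Newton iteration on 1/trigamma (limma's scheme),
# tolerance 1e-8.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(NaN)
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:75) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (-dif / y < 1e-8) break
    }
    y
  }, numeric(1))
}

# Moment-matching fit of (d0, s0^2) from per-feature variances.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2) # sample variance, limma convention
  if (is.na(evar) || evar <= 0) {
    # variances no more dispersed than sampling noise: pool completely
    list(d0 = Inf, s0_2 = mean(s2[ok]))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s0_2 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

# Estimated variance of the (nonzero) effect prior: limma's t-mixture
# moment estimator on the top fraction of |t| statistics.
tmixture_v0 <- function(tstat, v_unscaled, df_total, proportion = 0.01,
                        v0_lim = NULL) {
  ok <- is.finite(tstat)
  tstat <- abs(tstat[ok])
  ng <- length(tstat)
  ntarget <- ceiling(proportion / 2 * ng)
  if (ntarget < 1) return(0)
  p <- max(ntarget / ng, proportion)
  o <- order(tstat, decreasing = TRUE)[seq_len(ntarget)]
  t1 <- tstat[o]
  v1 <- rep_len(v_unscaled, ng)[o]
  r <- seq_len(ntarget)
  p0 <- 2 * pt(-t1, df = df_total)
  ptarget <- ((r - 0.5) / ng - (1 - p) * p0) / p
  v0 <- rep(0, ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- qt(ptarget[pos] / 2, df = df_total, lower.tail = FALSE)
    v0[pos] <- v1[pos] * ((t1[pos] / qtarget)^2 - 1)
  }
  if (!is.null(v0_lim)) v0 <- pmin(pmax(v0, v0_lim[1]), v0_lim[2])
  mean(v0)
}

#' Empirical-Bayes moderated paired t-test
#'
#' Shrinks each feature's variance toward a pooled prior before forming the
#' t-statistic: `s_tilde^2 = (d0*s0^2 + d*s^2) / (d0 + d)` with
#' `t_tilde = mean / (s_tilde / sqrt(n))` on `d0 + d` degrees of freedom.
#' The prior df `d0` and scale `s0^2` come from moment matching on the log
#' variances (with Newton-refined inverse trigamma, tolerance 1e-8); equal
#' variances give `d0 = Inf` and normal-limit p-values. The log-odds of
#' differential expression (B statistic) uses a prior proportion of 0.01
#' with the effect-variance estimated from the top t-statistics.
#'
#' @param diffs a [paired_differences()] object with >= 2 pairs; at least
#'   ~10 features are recommended for stable hyperparameter estimation.
#' @param proportion assumed prior proportion of differential features used
#'   for the B statistic.
#' @param d0_override force the prior df (0 disables shrinkage entirely,
#'   giving ordinary paired t).
#' @return Data frame `feature_id`, `mean_diff`, `t_moderated`, `df_total`,
#'   `p_raw`, `p_adj` (BH), `log_odds`; hyperparameters `d0` and `s0_2`
#'   are attached as attributes.
#' @export
moderated_t_test <- function(diffs, proportion = 0.01, d0_override = NULL) {
  stopifnot(inherits(diffs, "paired_differences"))
  d <- diffs$values
  n <- ncol(d)
  if (n < 2L) ct_abort("moderated t-test needs >= 2 pairs")
  m <- rowMeans(d)
  dfree <- n - 1
  s2 <- rowSums((d - m)^2) / dfree
  if (all(s2 == 0)) ct_abort("all features have zero variance")
  if (!is.null(d0_override)) {
    prior <- list(d0 = d0_override,
                  s0_2 = fit_variance_prior(s2, dfree)$s0_2)
  } else {
    prior <- fit_variance_prior(s2, dfree)
  }
  d0 <- prior$d0; s0_2 <- prior$s0_2
  if (d0 > 0 && is.finite(d0)) {
    s2_post <- (d0 * s0_2 + dfree * s2) / (d0 + dfree)
  } else if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
  } else {
    s2_post <- s2
  }
  df_total <- d0 + dfree
  tmod <- m / sqrt(s2_post / n)
  tmod[s2_post == 0] <- NA_real_
  p <- 2 * pt(-abs(tmod), df = df_total)
  v_unscaled <- 1 / n # variance of mean_diff in units of s^2
  df_b <- min(df_total, 1e6) # normal limit handled by large df
  v0 <- tmixture_v0(tmod, v_unscaled, df_b, proportion,
                    v0_lim = c(0.1, 4)^2) # coefficient-sd window 0.1..4
  r <- (v_unscaled + v0) / v_unscaled
  t2 <- tmod^2
  lods <- log(proportion / (1 - proportion)) - log(r) / 2 +
    (1 + df_b) / 2 * log((t2 + df_b) / (t2 / r + df_b))
  adj <- bh_adjust(p)
  ct_log(sprintf("moderated_t_test: d0 = %s, s0^2 = %.6g",
                 format(d0), s0_2))
  structure(data.frame(feature_id = rownames(d), mean_diff = m,
                       t_moderated = tmod, df_total = df_total,
                       p_raw = p, p_adj = adj$p_adj, log_odds = lods,
                       row.names = NULL, stringsAsFactors = FALSE),
            d0 = d0, s0_2 = s0_2, v0 = v0)
}
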