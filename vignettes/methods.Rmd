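---
title: "Methods: paired twin-discordance analysis and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired twin-discordance analysis and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotwin)
options(cotwin.verbose = FALSE)
```

# The analysis model

## Paired contrasts

Every statistic in the package operates on per-pair differences with one
fixed orientation, unaffected − affected. A single convention prevents sign
errors when methylation and expression are combined; the orientation is
stored on the `paired_differences` object and never re-inferred. The same
paired engine serves two front-ends: the co-twin contrast (pairing = twin
pair, condition = affection status) and the cell-type contrast (pairing =
individual, condition = CD4 vs CD8, restricted to unaffected twins by
default so disease status does not confound the cell-type signal).

## Per-feature paired t and FDR

For feature *g* with per-pair differences $d_1,\dots,d_n$:
$t_g = \bar d / (s_d/\sqrt n)$, two-sided p on $n-1$ df. Features with zero
variance get `NA` rather than $\pm\infty$ so the Benjamini–Hochberg
denominator stays honest; `NA`s are excluded from the step-up adjustment
$\tilde p_{(i)} = \min_{j \ge i} m\, p_{(j)}/j$. Tests are two-sided
throughout.

## Exhaustive sign-flip permutation null

The exact null for a paired design multiplies each pair's difference by
every sign vector in $\{-1,+1\}^n$ ("permuting affection status in all
possible combinations"; $2^{17} = 131{,}072$ arrangements for 17 pairs).
Because $\sum d_i^2$ is sign-invariant, $|t_b| \ge |t_{obs}|$ exactly when
$|\sum_i s_i d_i| \ge |\sum_i d_i|$, so enumeration reduces to signed sums
and is done as a blocked matrix product without compiled code. The observed
arrangement is counted, guaranteeing $p \ge 2/2^n$ (the global flip
preserves $|t|$); whether to include it is unstated in the source
literature, and including it is the standard choice that avoids p = 0.
Above a cap (default $2^{20}$) the function refuses and suggests Monte
Carlo mode, which uses the add-one estimator $p = (1+\#exceed)/(1+B)$.

## Moderated t for expression

Expression intensities are quantile normalized, log2-transformed
(offset 1.0, configurable, so zero intensities are tolerated), and tested
with an empirical-Bayes moderated t. Per-feature variances $s_g^2$ (each on
$d = n-1$ df) are modeled as scaled-F around a prior $(d_0, s_0^2)$
estimated by moment matching on $\log s_g^2$, with the inverse-trigamma
solved by Newton iteration (tolerance 1e-8). The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0+d)$ gives
$\tilde t_g = \bar d/(\tilde s_g/\sqrt n)$ on $d_0 + d$ df. When the
variances are no more dispersed than sampling noise the prior df is
reported as an `Inf` sentinel and the pooled mean variance is used, giving
normal-limit p-values. The B statistic (log-odds of differential
expression) uses a prior proportion of 0.01 with the effect-variance window
0.1–4 on the coefficient-SD scale; these conventions deliberately mirror
the standard empirical-Bayes implementation, which the test suite uses as
an independent oracle.

## Co-twin similarity and the technical contrast

Per-pair correlations are computed across the full feature vector —
Spearman for bounded, bimodal beta values, Pearson for log-scale
expression, mirroring field practice. The technical-vs-biological contrast
compares per-CpG mean |self − replicate| against per-CpG mean
|unaffected − affected|; per-CpG means (rather than pooled differences)
are used because the replicate experiment is described per CpG site.
Magnitudes, not signed differences, are contrasted. The two-sample KS test
uses the asymptotic Kolmogorov tail at effective size $nm/(n+m)$ —
appropriate at array scale (~26,700 CpGs) — with an exact lattice-path
computation below n = 50 when the samples are tie-free.

## Integration: the Δβ/logFC correlation

For each gene present on both platforms, Spearman's ρ (average ranks for
ties) is computed between the per-pair gene-level Δβ vector and the
per-pair logFC vector, over the pairs shared by both assays; genes with
fewer than 3 usable pairs are skipped and logged. The default p-value is
the t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df —
standard at n = 17, where exact enumeration is infeasible; full
permutation enumeration is available for $n \le 9$ and is always used when
$|\rho| = 1$, where the t-approximation degenerates to exactly 0. Ranking
is ascending p, ties broken by descending $|\rho|$, then gene id, so the
order is fully deterministic; the published "top 50" table that actually
contains 52 rows suggests ties at the cutoff were included there, but an
exact-k selection with a deterministic tie rule is the reproducible choice.
The top fraction is $\lceil f \cdot G\rceil$ genes (120 for f = 1% of
11,933).

## Enrichment

Overrepresentation is the one-sided hypergeometric upper tail
$P(X \ge k)$ with the platform-intersection universe as background. The
conservative EASE variant (observed count decremented by one) is available
behind a flag because the annotation tool the field uses defaults to it;
the plain Fisher tail is the package default since the original statistic
is not printed. Terms with zero overlap are excluded before BH adjustment.
Frequencies are reported as $100k/|input|$ rounded to one decimal.

# The synthetic cohort

## What it emulates

* ~27K-array promoter methylation: per gene a baseline logit-beta from a
  three-component mixture (unmethylated 55%, intermediate 15%, methylated
  30%; means −2.5/0/2.2, SDs 0.8/1/0.7 on the logit scale), probes
  scattered around their gene (SD 0.4), 1–4 CpGs per gene with weights
  0.32/0.28/0.24/0.16 so ~11,933 genes carry ~26,700 probes.
* MZ genetic identity: a per-pair, per-probe deviation (logit SD 0.15)
  shared by both twins and by technical replicates.
* Biological noise on the beta scale, heteroscedastic with SD proportional
  to $4\beta(1-\beta)$ and normalized so the probe-average SD equals the
  configured value (default 0.02). This mirrors the variance profile of
  beta values (tight near 0 and 1) and has a second virtue: the
  inverse-logit slope is $\beta(1-\beta)$, so a logit-scale effect and the
  noise share the same per-probe scale factor and planted signal-to-noise
  is uniform across baseline methylation.
* Co-twin correlation: the mean co-twin Spearman correlation is a
  decreasing function of the logit spread for spread multipliers ≥ 1
  (wider spread parks probes in the flat tails of the inverse logit, where
  noise scrambles ranks). The generator bisects this multiplier against
  the configured target (default 0.98, matching the reported 0.95–0.99
  range) on an 8,000-probe calibration subsample.
* Technical replicates: original value plus heteroscedastic noise with
  average SD `technical_noise_beta` (default 0.01, half the biological
  SD, reproducing the premise of the replicate experiment); both twins of
  the first 7 pairs are replicated by default.
* Expression: gene baselines N(8, 1.5) on the log2 scale, shared pair
  deviations (SD 0.3), individual noise SD 0.15 — these internal constants
  reproduce co-twin Pearson correlations of ~0.99. Values are emitted on
  the intensity scale ($2^x$) so the pipeline's own normalization and log
  transform are exercised.
* Planted dysregulation: each pair draws one latent discordance score
  $z_p$; planted gene *g* adds $a_g z_p$ to its co-twin logit-beta
  difference and $b_g z_p$ to its logFC, with coherent signs, so Δβ and
  logFC correlate across pairs with the planted sign. Effects are planted
  in the first cell type only, emulating the cell-type specificity of the
  motivating study and leaving the second cell type as a negative control.
* Cell-type structure: a configurable number of probes (default 1,300,
  ~5% of the array) get a ±1 logit offset in the second cell type, giving
  the within-individual CD4-vs-CD8 contrast a strong recoverable signal.

## Effect-size calibration

The stated experimental condition for recovery experiments is a population
Δβ/logFC correlation of ≈ 0.8 for planted genes. A single fixed logit-scale
effect SD cannot deliver that, because the per-gene Δβ noise depends on the
probe count and the heteroscedastic scale. The generator therefore sizes
effects per gene: with target Spearman $\rho^*$ (converted to the Gaussian
Pearson value $2\sin(\pi\rho^*/6)$), each assay receives signal-to-noise
$k=\sqrt{\rho_P/(1-\rho_P)}$, the methylation amplitude is
$a_g = 4k\sigma_g/\bar H_g$ (with $\sigma_g$ the gene's Δβ noise SD and
$\bar H_g$ its mean slope factor, capped at 2.5 logit units), and
$b_g = k\sqrt2\,\sigma_{expr}$. Verified at 400 pairs: realized per-gene
Pearson correlations 0.78–0.84 around the 0.81 target. Because $z_p$ is
shared by all planted genes, the sample SD of the 17 draws would otherwise
rescale every effect jointly (one unlucky cohort draw collapses the
delivered correlation to ~0.7); $z$ is standardized to unit sample SD so
the generator delivers the calibration it promises. The fixed
`latent_effect_*` SDs remain available (`target_population_rho = NULL`)
for users who want raw, uncalibrated effects.

## What a green test does not establish

The generator captures the correlation structure the analysis assumes, not
real arrays: no probe cross-hybridization or SNP artifacts, no
batch/position effects, no cell-subpopulation mixtures (a plausible source
of small co-twin differences in real T-cell data), no raw-intensity or
bisulfite-conversion modeling, and independent noise across probes (real
neighboring CpGs are correlated). Recovery rates on synthetic data
therefore bound what the statistics can do under their own assumptions —
they say nothing about biological confounding.

# Numerical choices and degenerate inputs

* Quantile normalization uses the mean-of-order-statistics reference; tied
  values receive the mean of the reference values their ranks span. It is
  idempotent to 1e-9 and column-permutation equivariant. "Quartile"
  normalization in vendor software is read as quantile normalization — the
  only defined matrix operation of that name; both beta and expression
  matrices can be normalized or left untouched via one flag.
* Methylation normalization beyond the input betas defaults to none: the
  upstream package actually used for it is unrecoverable from the text,
  and input betas are consumed as-is.
* Gene-level methylation is the unweighted mean of a gene's probes, no
  winsorization; missing values drop a feature from the affected contrast
  only.
* Sign-flip equality uses a relative tolerance of 1e-12 so float noise in
  the signed sums cannot flip a count; permutation p-values use |t|
  (matching the two-tailed convention used everywhere else).
* Zero-variance features: p = NA, excluded from FDR, counted in the log.
* The technical < biological noise invariant admits the all-zero
  degenerate case so the fully noiseless cohort (identical co-twins, all
  differences zero) remains constructible.
* Seeds: every stage derives its own 31-bit seed from the master seed and
  a stage label, so stages can be re-run in isolation and a fixed seed
  reproduces byte-identical outputs.

# Known limitations

* The exhaustive permutation engine is pure R; above ~2^20 arrangements it
  refuses rather than grinding (Monte Carlo mode covers larger designs).
* Exact Spearman p-values enumerate n! permutations and are limited to
  n ≤ 9; at |ρ| = 1 with larger n the tie-free closed form 2/n! is used.
* The B-statistic's effect-variance estimator follows the standard
  top-fraction moment method; with very few features (< ~100) it is
  unstable, as in any empirical-Bayes fit.
* The null-control experiment (no planted genes, per-CpG paired t + BH)
  declares zero findings in ~95% of seeds — exactly the nominal global
  false-positive rate; a 20-seed batch therefore occasionally shows two
  non-clean seeds, which is the calibrated behaviour of the test, not a
  defect.
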