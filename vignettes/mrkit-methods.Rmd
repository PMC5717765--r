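---
title: "Methods: two-sample Mendelian randomisation in mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomisation in mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The model

Mendelian randomisation treats genetic variants as instrumental variables
for a modifiable exposure. For variant $j$, let $\beta_{Xj}$ (SE $s_{Xj}$)
be its association with the exposure and $\beta_{Yj}$ (SE $s_{Yj}$) its
association with the outcome (log odds for a binary disease outcome), each
estimated in a separate GWAS sample. If variant $j$ is a valid instrument —
associated with the exposure, independent of confounders, and affecting the
outcome only through the exposure — then under a linear,
no-interaction structural model $\beta_{Yj} = \theta\,\beta_{Xj}$, and each
variant yields a Wald ratio estimate
$\hat\theta_j = \beta_{Yj}/\beta_{Xj}$ with first-order standard error
$s_{Yj}/|\beta_{Xj}|$. The delta approximation deliberately omits the
$\beta_X$-uncertainty term so that the per-variant weights
$w_j = \hat\theta_j^{-2}\text{SE}$, i.e. $w_j = \beta_{Xj}^2/s_{Yj}^2$,
match the fixed-effect inverse-variance weighting convention.

Four pooled estimators are provided:

* **IVW** (`mr_ivw`): $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$ with
  $\text{SE} = (\sum w_j)^{-1/2}$; algebraically identical to
  zero-intercept weighted least squares of $\beta_Y$ on $\beta_X$ with
  weights $s_Y^{-2}$ (asserted to 1e-10 in the tests). Fixed-effect only;
  it is the headline estimator. A single-variant exposure degenerates to
  the Wald ratio and is labelled `wald_ratio`.
* **Weighted median** (`mr_weighted_median`): the ratios are ordered and
  the $j$-th order statistic placed at percentile
  $100\,(S_j - w'_j/2)$ of the normalised cumulative weight $S_j$; the
  estimate interpolates linearly at the 50th percentile. Consistent while
  valid instruments carry more than half the total weight.
* **Penalised weighted median** (`mr_penalized_weighted_median`): each
  variant's heterogeneity with the unpenalised weighted median,
  $Q_j = w_j(\hat\theta_j - \hat\theta_{WM})^2$, is referred to a
  $\chi^2_1$ upper tail $q_j$, and the weight multiplied by
  $\min(1, 20\,q_j)$ before the median is recomputed. Homogeneous sets are
  untouched and the estimator reverts to the plain weighted median as the
  penalty constant grows; both facts are tested exactly.
* **MR-Egger** (`mr_egger`): weighted regression of $\beta_Y$ on $\beta_X$
  with a free intercept (weights $s_Y^{-2}$) after orienting every variant
  to $\beta_X \ge 0$. The slope estimates $\theta$ under the weaker InSIDE
  assumption; the intercept estimates the average directional pleiotropic
  effect and its test is the pleiotropy diagnostic.

## Numerical and inferential choices

* **Median SEs by parametric bootstrap** in ratio space: each
  $\hat\theta_j$ is resampled from $N(\hat\theta_j, s_{\theta j}^2)$ and
  the (penalised) median recomputed; the SE is the SD of the resampled
  estimates (default 1000 draws, seed mandatory). How the median SEs of
  published analyses were obtained is generally unstated, so exact CI
  widths for the median methods are not expected to reproduce
  bit-for-bit; resampling the ratio directly keeps the bootstrap
  independent of the exposure-side noise model.
* **Egger SE inflation**: coefficient SEs are the sigma-free
  $(X'WX)^{-1}$ values multiplied by $\max(1, \hat\sigma)$, so
  overdispersion widens intervals but underdispersion never narrows them;
  computed directly from the design matrix so an exactly-fitting line
  stays finite. Egger p-values use $t_{n-2}$; IVW and median p-values use
  the normal distribution.
* **Strict thresholds**: with $m$ risk factors examined,
  `bonferroni_classify` calls $p < 0.05/m$ significant and $p < 0.05$
  suggestive, both strictly; $p = 0.05/m$ exactly is suggestive. Tested at
  the boundary.
* **Display rounding**: ORs and CIs to 2 decimals and p-values to 2
  significant figures in the forest table, with a full-precision
  (`%.17g`) machine-readable companion, so pipeline re-runs can be
  compared byte for byte.

## Harmonisation

Exposure and outcome tables are joined on variant identifier and the
outcome effect re-expressed per copy of the exposure's effect allele: a
swapped allele pair flips the sign of $\beta_Y$ and replaces the frequency
by its complement. Allele pairs are compared after optional strand
complementing (A–T, C–G); `strand = "drop"` disables this and treats
complement-only matches as incompatible, since which behaviour a given
published analysis used is rarely stated. Pairs that match neither way are
dropped with reason "incompatible alleles".

Palindromic variants (A/T, C/G) cannot be strand-resolved from labels.
The default policy orients them by comparing both effect-allele
frequencies to 0.5, and drops the variant when either frequency lies
within 0.08 of 0.5 (0.42–0.58) or is missing — inside that band the
orientation is not reliably inferable from frequency. A drop-all policy is
available. Every flip and drop is recorded in the instrument set's
provenance log, and the pipeline's run report accounts for every input
variant as either a retained instrument or a logged drop.

Instrument selection utilities mirror standard practice: `prune_ld` keeps
a greedy lowest-p-value-first subset with all pairwise $r^2$ below 0.2
(ties broken lexically so selection is deterministic; a variant absent
from the LD matrix is a hard error), and `apply_proxy_map` substitutes
user-supplied proxies with $r^2 > 0.9$ for instruments missing from the
outcome study. No LD reference panel is queried; both LD and proxies are
inputs.

## The synthetic-data generator

`simulate_summary_stats` generates both tables directly at summary level
(no individual genotypes — the analysis consumes only summary statistics,
and this keeps validation runs in milliseconds):
$\beta_{Xj} \sim N(\gamma_j, s_{Xj}^2)$ and
$\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, s_{Yj}^2)$, with
$\alpha_j = 0$ for valid instruments and
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ for the configured invalid
fraction. Defaults: true effect magnitudes $|\gamma_j|$ uniform on
0.02–0.1 with random sign, exposure SEs uniform on 0.003–0.009 (per-variant
F statistics from single digits to several hundred, spanning weak and
adequate instrument regimes), outcome SEs uniform on 0.015–0.035 (typical
of a case-control GWAS with tens of thousands of samples), allele
frequencies uniform on 0.05–0.95, and a 20% chance of a palindromic
allele pair so harmonisation paths are exercised. Identical seeds give
bit-identical output. `corrupt_allele_encoding` applies random
allele-label swaps (negating beta, complementing frequency) and strand
flips with a manifest, and the tests assert that harmonisation restores
the uncorrupted instrument set exactly.

For directional-pleiotropy scenarios (median robustness, Egger intercept
recovery) the generator is configured with all-positive $\gamma_j$
(`prob_positive = 1`). This is an identity requirement, not a
convenience: directional pleiotropy is defined relative to the
exposure-increasing allele, and with random-sign $\gamma$ a constant
$\mu_\alpha$ becomes balanced in ratio space, so no estimator would (or
should) register it as directional.

What the generator does not emulate: LD between instruments (instruments
are independent, as they are post-pruning in a real analysis),
exposure–outcome sample overlap (a two-sample setting is assumed), allele
frequency differences between the two studies, and selection of
instruments on genome-wide significance (winner's curse). Passing tests
therefore validate the estimators and plumbing under the stated model,
not robustness to those additional features of real data.

## Validation problem sizes

The simulation-based checks use 500 replicates of 100 variants for
parameter recovery (true $\theta = 0.3$), CI coverage (0.95 ± 0.03 band)
and the invalid-instrument robustness comparison (40% invalid weight,
$\mu_\alpha = 0.05$), 200 replicates for Egger intercept recovery, and
100 replicates for type-I control of the Bonferroni classification at
$\theta = 0$ over 24 tests. These sizes give Monte-Carlo standard errors
of roughly 0.0015 on mean estimates while the whole suite completes in
well under a minute.

## Known limitations

* **MR-Egger attenuates under weak instruments.** With measurement error
  in $\beta_X$, the Egger slope is diluted by roughly
  $I^2_{GX} = \mathrm{Var}(|\gamma|)/(\mathrm{Var}(|\gamma|) +
  \overline{s_X^2})$, about 0.93 under the generator defaults. At 500
  replicates the resulting ~2% deterministic attenuation of
  $\theta = 0.3$ is comparable to, and can exceed, the Monte-Carlo error
  of the mean, and the corresponding recovery assertion fails by a small
  margin. This is a documented property of the estimator (the "no
  measurement error" assumption is violated at finite instrument
  strength), not an implementation defect; the exactness tests on
  noiseless data and the intercept-recovery test pass. The other three
  estimators recover the truth within Monte-Carlo error.
* The overall F statistic from $(r^2, n, k)$ and the mean per-variant F
  answer slightly different questions and can differ substantially for
  heterogeneous instruments; both are reported and labelled, and neither
  is treated as canonical.
* Fixed-effect IVW is the only headline pooling rule; heterogeneity-robust
  (multiplicative random-effects) variants are deliberately out of scope
  beyond the median and Egger sensitivity suite.
* Single-variant exposures admit no sensitivity analysis; they are routed
  to the Wald ratio and labelled so that downstream tables make the low
  precision visible.
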