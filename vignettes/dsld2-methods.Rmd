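---
title: "Methods: the D-squared estimator and its benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the D-squared estimator and its benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsld2)
```

# The model

For gene $g$ observed in $k$ studies, the random-effects model for the
observed effect size $y_{ig}$ is

$$y_{ig} = \mu_g + \xi_{ig} + \varepsilon_{ig}, \qquad
\xi_{ig} \sim N(0, \tau^2_g), \quad
\varepsilon_{ig} \sim N(0, \sigma^2_{ig}),$$

where $\sigma^2_{ig}$ is the within-study sampling variance (treated as
known, estimated from the data) and $\tau^2_g$ the between-study variance.
Given an estimate $\hat\tau^2_g$, the pooled mean is the inverse-variance
weighted average with weights $\omega^*_{ig} = (\hat\tau^2_g +
\hat\sigma^2_{ig})^{-1}$; its variance is $1/\sum_i \omega^*_{ig}$, the 95%
interval uses the fixed 1.96 normal multiplier, and the two-sided p-value
comes from the standard normal distribution of $z = M^*_g /
\sqrt{\mathrm{Var}(M^*_g)}$. Setting $\tau^2_g = 0$ recovers the
fixed-effects model (FEM) exactly — `pool(y, s2, 0)` is bit-identical to
the FEM dispatch, which the tests assert.

# Between-study variance estimators

All estimators share Cochran's statistic at fixed-effects weights
$\omega_{ig} = \hat\sigma^{-2}_{ig}$,
$Q_g = \sum_i \omega_{ig}(y_{ig} - M_g)^2$, and the moment denominator
$S = \sum_i \omega_{ig} - \sum_i \omega^2_{ig} / \sum_i \omega_{ig}$.

* **DSL** — $\max\{0, (Q_g - (k-1))/S\}$, the classical moments estimator.
* **PM** — the root of the generalized-Q equation
  $\sum_i \omega^*_{ig}(y_{ig} - M^*_g(\tau^2))^2 = k - 1$. The left side
  is continuous and non-increasing in $\tau^2$, so the root is unique; we
  bracket it by geometric expansion of the upper bound and solve with
  `uniroot` to $10^{-10}$, truncating at 0 when the equation is already
  below $k-1$ there.
* **RML** — restricted maximum likelihood under the profile restricted
  log-likelihood (with the $-\tfrac12\ln\sum_i(\sigma^2_{ig} +
  \tau^2)^{-1}$ adjustment), maximized by scoring iterations
  $\tau^2 \leftarrow \sum_i w_i^2(e_i^2 - \sigma^2_{ig})/\sum_i w_i^2 +
  1/\sum_i w_i$ started at the DSL estimate, with the mean profiled out at
  each step; converged when successive values differ by less than
  $10^{-8}$ (at most 100 iterations), negatives truncated to 0. On rare
  instances the scoring map oscillates; the implementation then falls
  back to bracketed root-finding on the REML score, which has the same
  zero. The returned value is checked against a grid-search maximizer of
  the likelihood in the tests.
* **SJ** — the two-step estimator with crude initial value
  $\tau^2_0 = \max\{0.01,\ \sum_i(y_{ig}-\bar y_g)^2/(k-1) -
  \sum_i\hat\sigma^2_{ig}/k\}$ followed by one reweighting step. The 0.01
  floor makes the estimate strictly positive whenever the effects
  disperse at all. Note that other software initializes this estimator
  differently (e.g. without subtracting the mean within-study variance),
  which changes its numerical value; we therefore cross-check SJ against
  the closed form rather than against another package.
* **DSLR2** — after a DSL first pass, the relative drop in weighted
  dispersion $R^2_g = 1 - \sum_i \omega^*_{ig}(y_{ig}-M^*_g)^2 / Q_g$,
  truncated to $[0, 1]$ and used directly in place of a between-study
  variance in the pooling weights. $R^2$ is a unitless fraction, not a
  variance; using it as if it were one mirrors the two-step structure of
  D-squared and is retained here as a comparator exactly because its
  behaviour differs qualitatively from the variance-scale estimators.
  When $Q_g = 0$ the ratio is undefined and the statistic is defined as 0.
* **DSLD2** — the package's centrepiece. After the DSL first pass,
  compute the random-effects pooled mean $M^*_g$ and the generalized Q at
  random-effects weights, $S_{MM,g} = \sum_i (y_{ig} -
  M^*_g)^2/(\hat\sigma^2_{ig} + \hat\tau^2_{g,\mathrm{DSL}})$, and set
  $$D^2_g = \frac{Q_g - S_{MM,g}}{S}.$$
  Moving from fixed-effects to random-effects weights can only reduce the
  weighted dispersion, so $D^2_g \ge 0$, with equality exactly when the
  DSL estimate is 0 (then $S_{MM} = Q$); tiny negative values from
  floating-point roundoff are clamped. Under equal within-study variances
  $D^2$ coincides with DSL, a closed-form identity the tests assert. The
  DSLD2 *method* re-pools with $D^2_g$ in the weights. A property suite
  verifies that $D^2_g$, viewed as a function of the $\tau^2$ plugged
  into $M^*$ and $S_{MM}$, is non-decreasing.

Heterogeneity is summarized as $I^2 = \hat\tau^2/(\hat\tau^2 + \tilde
s^2)$ with the moment-based typical within-study variance $\tilde s^2 =
(k-1)\sum_i\omega_{ig} / ((\sum_i\omega_{ig})^2 - \sum_i\omega^2_{ig})$.
This form (rather than the $Q$-only expression) is used because it lets
$I^2$ vary with the estimator, which is what the benchmark compares.

# Effect-size measures

From per-study case/control summaries the package computes either the raw
mean difference (MD), with variance $s^2_c/n_c + s^2_t/n_t$, or the
standardized mean difference (SMD): Cohen's $d$ on the pooled standard
deviation with Hedges' small-sample correction $J = 1 - 3/(4\,\mathrm{df}
- 1)$ applied by default (the convention of effect-size meta-analysis of
expression data; `hedges = FALSE` gives raw $d$), and large-sample
variance $(n_c + n_t)/(n_c n_t) + y^2/(2(n_c + n_t))$. Genes with zero
pooled variance are excluded with a warning rather than patched with a
small $\epsilon$, because a zero within-study variance would mean
infinite weight downstream.

# The expression benchmark generator

`simulate_dataset()` emulates a multi-study microarray comparison: 5
studies of 2000 genes with 2N samples each (N controls then N cases; the
benchmark uses 2N = 100, and the sample-size sweep 2N = 10..220). Genes
1–800 form 40 clusters of 20; each (cluster, study) pair draws its own
correlation matrix by standardizing an inverse-Wishart draw with scale
$0.5I + 0.5J$ and 60 degrees of freedom (exchangeable prior correlation
0.5), and samples are multivariate normal under it. The remaining 1200
genes are i.i.d. normal with a per-study variance drawn once from
U(0.8, 1.2). Genes 1–1000 are differentially expressed in $k_g$ studies
($k_g = 1..5$ in consecutive blocks of 200): the affected studies are a
uniformly random subset of size $k_g$, and in each a shift drawn from
U(0.5, 3) is added to the case samples only. The generator is
bit-reproducible from its seed, and which 800 genes carry the cluster
correlation is a labelling choice that leaves every per-gene marginal
distribution (hence every expected metric) unchanged.

Three truth labellings grade a caller: **H1**, effects in *all* studies
(200 genes at defaults); **H2**, in *at least one* (1000); **H3**, in at
least $r$ (600 at the default $r = 3$). The headline benchmark summary
(`benchmark_metrics()`) reports calls at raw $p < 0.05$ (DE1) and at
Benjamini–Hochberg adjusted $p < 0.05$ (DE2). Because the pooled z-test's
null hypothesis is "no effect in any study", the natural error standard
for raw calls is the union truth, and `fdr1` is the empirical FDR of the
DE1 set against H2; the adjusted-threshold `fdr2` is scored against the
stricter majority truth H3, the discovery standard a BH-controlled screen
is aimed at. Scoring either FDR against H1 would be incoherent: far more
than 200 genes carry real signal, so a well-behaved caller necessarily
"fails" such a standard. For the same reason the large-sample
precision/FPR sweep grades p < 0.05 calls against the union truth.

What the generator does *not* emulate: platform and batch effects,
missing values, normalization artifacts, non-normal expression noise, or
correlation between studies. Passing benchmarks here therefore show
correct behaviour of the estimators under the stated sampling model, not
performance on raw microarray data.

# The Monte Carlo estimator study

`run_mc()` measures bias and RMSE of the six heterogeneity estimators
directly. Each iteration draws $k \in \{5,10,20,40,80\}$ studies with
per-arm sizes $\mathrm{round}(N(40, (40/3)^2))$ floored at 2,
observations $N(0, 10)$ in controls and $N(\mu_i, 10)$ in cases with
$\mu_i \sim N(0, \tau^2)$, $\tau^2 \in \{0, 1\}$, and 1000 iterations per
setting. On the MD scale the generating $\tau^2$ is the estimand; on the
SMD scale dividing by the common observation variance gives the estimand
$\tau^2/\sigma^2 = \tau^2/10$, and bias/RMSE are scored against that
value (the raw $\tau^2$ would be on the wrong scale). Monte Carlo
standard errors are reported alongside so "close bias curves" statements
are testable as differences within sampling error; at $\tau^2 = 0$ every
estimator is non-negative and hence biased upward, another asserted
property.

# Numerical choices and test problem sizes

Root-finding tolerances are $10^{-10}$ (PM) and $10^{-8}$ (RML); the
p-value floor is $10^{-300}$ so $-\log_{10} p$ stays finite; degenerate
inputs (a single study, non-positive variances, one study holding all
weight) raise errors rather than returning NaN. Zero-denominator
confusion metrics are reported as 0 with an `undefined` flag so sweep
tables stay numeric.

The test suite runs the full benchmark at its native scale (2000 genes,
5 studies, 2N = 100) over 20 seeds, the sample-size sweep at 3 seeds per
setting, the Monte Carlo study at $k \in \{5, 40\}$ with 1000 iterations,
and the property suites at $10^4$ random instances — sizes chosen to make
seed-to-seed Monte Carlo error small relative to the effects being
asserted while keeping a full run in the low minutes.

# Known limitations

* The SMD variance is the large-sample form; at very small arms (n < 5)
  it understates uncertainty slightly.
* DSLR2 mixes a unitless fraction into variance-scale weights by design
  (see above); interpret its pooled variance accordingly.
* The normal-theory p-values ignore the uncertainty of $\hat\tau^2_g$;
  with few studies all methods are somewhat anti-conservative under
  strong heterogeneity, which is precisely the regime the benchmark
  probes.
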