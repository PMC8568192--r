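---
title: "A joint Poisson mixture model for de novo mutation burden across traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A joint Poisson mixture model for de novo mutation burden across traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmjoint)
```

## The model

Trio sequencing studies count de novo mutations (DNMs) per gene in cohorts
of affected probands. For a gene with mutability $\mu_i$ (the per-generation
probability of a damaging-class DNM arising on one haploid genome), a cohort
of $N$ trios is expected to contribute $2N\mu_i$ DNMs under the null.
`dnmjoint` models the observed count for one trait as a two-component
mixture,

$$Z_i \sim \mathrm{Bernoulli}(\pi), \qquad
  Y_i \mid Z_i = 0 \sim \mathrm{Poisson}(2N\mu_i), \qquad
  Y_i \mid Z_i = 1 \sim \mathrm{Poisson}(2N\mu_i\gamma_i),$$

where $\gamma_i > 1$ is the relative risk in risk genes. Functional
annotations enter through an exponential link,
$\gamma_i = \exp(X_i^\top\beta)$, with $X_i$ a gene-level feature vector
(leading intercept) and $\beta$ the effect sizes. With no annotations
$X_i$ degenerates to the intercept and all risk genes share one
relative risk $e^{\beta_0}$.

For two traits the latent state becomes a four-class indicator
$Z_i \in \{00, 10, 01, 11\}$ — associated with neither trait, only the
first, only the second, or both — with prior
$\pi = (\pi_{00}, \pi_{10}, \pi_{01}, \pi_{11})$. Counts
$(Y_{i1}, Y_{i2})$ are conditionally independent Poisson draws whose means
carry the trait's relative risk exactly in the classes that include that
trait's risk. The marginal risk proportions are $\pi_{10}+\pi_{11}$ and
$\pi_{01}+\pi_{11}$; the gap between $\pi_{11}$ and the product of the
margins measures global pleiotropy, with $\pi_{11} = $ margin$_1 \times$
margin$_2$ the independence point. Because DNMs are rare, genes are treated
as independent, and the log-likelihood is
$\sum_i \log \sum_l \pi_l \Pr(Y_{i1}, Y_{i2} \mid Z_{il}=1)$.

This class structure is fixed throughout the package in the order
$(00, 10, 01, 11)$: column order of posteriors, of `pi`, and of every
on-disk output.

## Estimation

Parameters $\Theta = (\pi, \beta_1, \beta_2)$ are estimated by EM
(`fit_single()`, `fit_multi()`):

* **E-step** — each gene's class posterior
  $Z_{il} = \pi_l \Pr(Y_i \mid l) / \sum_{l'} \pi_{l'}\Pr(Y_i \mid l')$.
  All class likelihoods are evaluated as Poisson log densities and the
  normalization is a log-sum-exp, so large mean/count discrepancies cannot
  underflow. The normalizer doubles as the marginal log-likelihood,
  giving the EM trace for free.
* **M-step for $\pi$** — the analytic update
  $\pi_l = \sum_i Z_{il} / M$.
* **M-step for $\beta$** — with an intercept-only design the weighted
  Poisson problem has the closed form
  $\beta_0 = \log(\sum_i w_i Y_i / \sum_i w_i \, 2N\mu_i)$, with
  $w_i$ the posterior probability of the trait's risk classes. With
  annotations there is no closed form and the package runs a damped
  Newton-Raphson on the concave objective
  $Q(\beta)=\sum_i w_i\,(Y_i X_i^\top\beta - 2N\mu_i e^{X_i^\top\beta})$,
  using the exact gradient and Hessian.

Choices the model statement leaves open are resolved as follows, and are
deliberately boring:

* **Initialization.** $\pi^{(0)} = (0.90, 0.04, 0.04, 0.02)$ for two traits
  ($(0.9, 0.1)$ for one); each intercept starts at the moment estimate
  $\log(\max(1.5, \sum Y / \sum 2N\mu))$, other coefficients at 0. This
  starts in the interior with $\gamma > 1$, as the burden assumption
  expects. The default fit is deterministic — no random restarts.
* **Stopping.** EM stops when the marginal log-likelihood gains less than
  a relative $10^{-8}$ per iteration, with a cap of 5,000 iterations; the
  inner Newton loop stops at gradient $\infty$-norm below $10^{-8}$ or 100
  steps. Non-convergence is a warning plus `converged = FALSE`, never an
  error, so grids keep running.
* **Safeguards.** Each Newton step is halved (up to 30 times) until $Q$
  does not decrease — $Q$ is concave in $\beta$, so this is globally
  convergent — and a numerically singular Hessian gets a relative ridge
  ($10^{-8}\,\mathrm{tr}(H)/p$). If a class's posterior mass collapses
  below $10^{-12} M$, its $\pi_l$ is floored at $10^{-12}$ and the vector
  renormalized, keeping the E-step defined on degenerate data.
* **No $\gamma > 1$ constraint.** The burden assumption motivates the
  model but is not imposed on the estimator; a fitted intercept $\le 0$
  (i.e. $\hat\gamma \le 1$) triggers a warning instead. On data with no
  real signal $\hat\gamma$ drifts to $\approx 1$, the class likelihoods
  merge, and $\pi$ becomes unidentifiable (at $\gamma = 1$ the likelihood
  is exactly flat in $\pi$); the warning plus an empty rejection set is
  the intended behavior there, not a recovery of $\pi_{00} = 1$.

On 10,000 genes a two-trait annotated fit converges in well under a second,
which is what makes the replicate grids below practical.

## Annotations: collapsing and feature selection

Variant-level annotations (deleteriousness scores, allele frequencies,
splicing scores) are collapsed to gene level by `collapse_to_gene()` as the
sum of the annotation values over the gene's observed DNMs. The
justification is a first-order expansion of the likelihood ratio of a
gene's counts under risk versus null: for small variant-level effects and
*centered* annotations, that sum is the sufficient gene-level statistic.
Accordingly continuous scores are centered by default (subtracting the
DNM-wide mean) before summing; binary flags such as LoF indicators are
summed uncentered, so their collapsed value is the gene's flagged-DNM
count. Genes with no DNMs score zero. Missing variant-level values are
imputed with the annotation's DNM-wide mean and tallied in a message — an
arbitrary but transparent convention.

`standardize_features()` then scales every gene-level feature to mean 0,
standard deviation 1 (population $1/n$ scaling — the choice is arbitrary
and fixed; collapsed binary counts are standardized along with continuous
scores). Constant columns are dropped with a warning.

Feature selection is two-stage and runs per trait on single-trait fits:

1. `prune_correlated()` — a greedy scan in input column order that drops
   any feature whose Pearson correlation with an already-kept feature
   exceeds 0.7. The default compares the *signed* correlation, taking the
   rule literally; `absolute = TRUE` switches to $|r|$ since either
   reading is defensible. First-in-order wins ties, which makes the report
   reproducible byte for byte.
2. `select_by_effect_size()` — fit the single-trait annotation model, keep
   features with $|\hat\beta| > 0.01$, refit on the survivors.

A caveat worth knowing: at realistic scales (10,000 genes, ~1,000 risk
genes) the sampling noise of a null feature's effect estimate is itself
around 0.02, so the 0.01 screen reliably keeps informative features but
only removes a pure-noise feature some of the time. Treat stage 2 as a
coarse filter, not a significance test.

## Inference

`jlfdr()` computes, per gene and trait, the joint local false discovery
rate — the posterior probability that the gene is null for that trait given
*both* counts: for trait 1, $\Pr(Z_{00}+Z_{01}=1 \mid Y_{1}, Y_{2})$, i.e.
the sum of two posterior columns. `fdr_threshold()` turns these into a
rejection set with global FDR control: sort ascending, form running means
$\mathrm{Fdr}(a) = a^{-1}\sum_{b\le a}\mathrm{Jlfdr}_{(b)}$, take the
largest $a$ whose running mean is at or below $q$, and reject everything
at or below the $a$-th sorted value. Ties at the threshold are all
rejected — the rejection region is $\{\mathrm{Jlfdr} \le t(q)\}$, and a
set definition cannot split tied genes. By construction the mean Jlfdr of
the rejected set is at most $q$, which the tests assert on every run.
The default level is $q = 0.05$.

Two interpretive choices: the fitted posterior is plugged in directly
(empirical Bayes; no propagation of uncertainty in $\hat\Theta$), and
single-trait testing reuses the identical thresholding machinery on the
two-class posterior.

## The simulation engine

`sim_config()` + `run_grid()` reproduce the two generative regimes used to
validate the method:

* **Correctly specified** (`simulate_true_model()`): classes from
  $\mathrm{Multinomial}(1, \pi)$, per-trait annotations i.i.d.
  Bernoulli(0.5), $\gamma_i = \exp(X_i^\top\beta)$ from *all* annotations,
  Poisson counts. The `observed` mask returns only a subset of annotations
  to the analyst (the default power studies expose two of three), so fits
  run under realistic partial information.
* **Misspecified** (`simulate_misspecified()`): annotations act on the
  *class membership* through a multinomial-logistic link — which
  factorizes into two independent per-trait logistic draws — while the
  relative risk is a constant (default 25). This probes robustness when
  the exponential-link assumption is wrong.

Mutabilities are drawn from a truncated log-normal,
$\log_{10}\mu \sim N(-5, 0.7)$ on $[-8, -3.5]$, sampled by inverse CDF. This
is a synthetic stand-in chosen to match the scale and spread of
damaging-class mutabilities in large exome constraint resources; real
per-gene mutability tables can be supplied instead wherever a gene table is
read. What the generator does *not* emulate: the heavy right tail of gene
length, correlation between mutability and annotations, cohort-specific
calling artifacts, and annotation distributions richer than Bernoulli —
so passing simulations demonstrate correctness of the machinery under the
stated model, not performance on any particular real cohort.

Replicate $r$ of a setting always uses seed `base_seed + r`, making grids
deterministic and trivially parallelizable. `evaluate_replicate()` scores
power, the empirical false discovery proportion
(false rejections / max(1, rejections)), type-I error, and AUC; AUC ranks
genes by $1-\mathrm{Jlfdr}$ with ties counted one half. Summaries report
means with Monte-Carlo standard errors and make no distributional
assumptions.

The package's own validation runs at the study scale: 10,000 genes, 50
replicates per setting, cohorts between 2,000 and 10,000 trios. The
four-method power comparison (single/multi × with/without annotations) is
run at 5,000 trios per cohort, the middle of the sizes the estimation
studies cover, with shared proportion 0.09 and strong (0.5) annotation
effects where the orderings are cleanest.

## Limitations

* Two traits only; the latent class count grows as $2^K$ in the number of
  traits, and nothing here attempts $K > 2$.
* No standard errors or intervals on $\hat\Theta$; inference is purely the
  empirical-Bayes posterior.
* Mutabilities are consumed as input; estimating $\mu_i$ from sequence
  context is out of scope.
* The Jlfdr threshold controls FDR given the fitted model; gross model
  misspecification beyond the scenarios simulated here (e.g. overdispersed
  counts) is uncharted.
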