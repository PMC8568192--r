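# dnmjoint

Joint mixture-model analysis of de novo mutation (DNM) counts across traits.

## The problem

Trio sequencing studies catalogue mutations present in an affected child but
in neither parent. Genes in which damaging DNMs recur more often than the
mutation rate predicts are candidate risk genes, but per-gene counts are
tiny (most genes contribute 0 or 1 DNMs even in thousands of trios), and
related disorders — e.g. congenital heart disease and autism — share risk
genes. Analyzing cohorts one at a time wastes that shared signal.
`dnmjoint` is for statistical geneticists who have per-gene DNM counts from
one or two case cohorts, per-gene mutabilities, and (optionally) functional
annotations, and who want calibrated risk-gene discovery that borrows
strength across traits.

## The model

For gene *i* with mutability μᵢ in a cohort of *N* trios, the null expected
DNM count is 2*N*μᵢ. Counts follow a Poisson mixture over a latent
four-class association indicator Zᵢ ∈ {00, 10, 01, 11} (neither trait,
trait 1 only, trait 2 only, both) with prior π:

    Y_i1 | Z_i ~ Poisson(2 N₁ μᵢ γ_i1)   with γ_i1 = exp(X_i1ᵀ β₁) in classes 10, 11, else 1
    Y_i2 | Z_i ~ Poisson(2 N₂ μᵢ γ_i2)   with γ_i2 = exp(X_i2ᵀ β₂) in classes 01, 11, else 1

Annotations Xᵢ enter the relative risk γ through an exponential link;
without annotations γ degenerates to a single shared relative risk per
trait. Parameters (π, β₁, β₂) are estimated by EM — analytic M-steps where
they exist, damped Newton-Raphson where they do not. Genes are then ranked
by the joint local false discovery rate
Jlfdr₁(Yᵢ₁, Yᵢ₂) = Pr(Z₀₀ + Z₀₁ = 1 | Yᵢ₁, Yᵢ₂), and the rejection set is
chosen by the running-mean rule: sort Jlfdr ascending, reject down to the
largest rank whose cumulative mean is ≤ q (default q = 0.05), which
controls the global FDR. π₁₁ versus the product of the marginal risk
proportions measures pleiotropy between the traits.

The package also ships variant-to-gene annotation collapsing with two-stage
feature selection (correlation pruning at r > 0.7, then an effect-size
screen at |β̂| > 0.01), and a simulation engine that generates data under
the model — and under a misspecified logistic-latent-class variant — to
measure power, FDR, type-I error, and AUC over replicate grids.

## Worked example

Simulate a two-trait study (10,000 genes, 5,000 trios per cohort, 10% risk
genes per trait half of them shared, two Bernoulli annotations with effects
0.3 on top of a baseline log relative risk of 3), fit, and test:

```r
library(dnmjoint)

cfg <- sim_config(m_genes = 10000, n1 = 5000, n2 = 5000,
                  pi = pi_from_margins(0.1, 0.1, 0.05),
                  beta1 = c(3, 0.3, 0.3), beta2 = c(3, 0.3, 0.3),
                  base_seed = 42)
sim <- simulate_true_model(cfg, rep_index = 1)

fit <- fit_multi(sim$table, cohort_info(5000, 5000),
                 sim$designs[[1]], sim$designs[[2]])
fit
#> DNM mixture fit (2 traits, 10000 genes)
#>   converged: TRUE after 10 EM iterations
#>   log-likelihood: -15511.38353
#> Mixture parameters (2 traits)
#>   pi:    00=0.8525  10=0.05363  01=0.04749  11=0.0464
#>   beta1: 3.007 0.2778 0.2966
#>   beta2: 2.987 0.3332 0.2778
```

The fitted class proportions recover the generating values
(π = 0.85, 0.05, 0.05, 0.05), as do the annotation effects (3, 0.3, 0.3).
Testing at q = 0.05:

```r
res <- run_inference(fit, q = 0.05)
head(res[, c("gene_id", "y1", "y2", "jlfdr_t1", "sig_t1", "sig_t2")], 4)
#>   gene_id  y1 y2  jlfdr_t1 sig_t1 sig_t2
#> 1  g04299 110  3 3.67e-128   TRUE  FALSE
#> 2  g00407 105 53 2.45e-121   TRUE   TRUE
#> 3  g06086  90 38 2.08e-108   TRUE   TRUE
#> 4  g01925  84 77  1.42e-99   TRUE   TRUE

sum(res$sig_t1)
#> [1] 705

evaluate_replicate(res, sim$truth, trait = 1)
#>   power    fdr   type1   auc n_rejected
#> 1 0.672 0.0426 0.00333 0.959        705
```

705 genes are declared trait-1 risk genes; against the simulation truth
that is 67% power with a realized false discovery proportion of 0.043 —
under the nominal 0.05. `run_grid()` repeats this over settings ×
replicates × methods (single/multi trait, with/without annotations) and
`summarize_grid()` reports means with Monte-Carlo standard errors.

A thin command-line wrapper with `simulate`, `collapse`, `select-features`,
`fit-single`, `fit-multi`, `test`, and `grid` subcommands is installed at
`system.file("cli", "dnmjoint.R", package = "dnmjoint")`.

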