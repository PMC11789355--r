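# multipcg

Implicating putative causal genes (PCGs) for a complex trait by combining
GWAS evidence with molecular-QTL evidence for **multiple gene products** —
typically expression (*E*) and protein abundance (*P*) — in one
empirical-Bayes model-selection framework.

## The problem and the model

A TWAS or PWAS association between a genetically predicted gene product and
a trait can be an artifact of linkage disequilibrium (LD hitchhiking);
colocalization evidence is robust to that artifact but underpowered on its
own. `multipcg` merges both, across products, under the structural model

```
E = G·βE + θE·U + eE
P = G·βP + θP·U + eP
Y = G·βY + γ·E + δ·P + θY·U + eY
```

and selects among four mechanism models per gene — `M0` (γ = δ = 0), `ME`
(γ ≠ 0 only), `MP` (δ ≠ 0 only), `ME+P` (both). Evidence enters in two
forms:

* the joint association of the trait with the pair of genetically
  predicted products, `Y ~ γ·Ê + δ·P̂`, whose regression R² equals the
  squared canonical correlation between `Y` and `(Ê, P̂)`; the Wald
  statistic feeds model-specific Bayes factors (computable from
  individual-level data or from GWAS z-scores + an LD matrix);
* gene-level colocalization probabilities per product, entering a
  truncated prior `π·f(p_coloc,E, p_coloc,P)` so that genes without even
  modest colocalization evidence can never be called causal.

Two global hyperparameters are estimated by EM across genes: the causal
mixture proportion `π` and the conditional mechanism proportions
`(h_E, h_P, h_E+P)`. Each gene then gets a **gene probability of putative
causality** (GPPC; its complement is a local false discovery rate used for
Bayesian FDR control) and **gene-product relevance probabilities** such as
`Pr(E affects Y | data) = Pr(ME|data) + Pr(ME+P|data)`.

The package also ships a minimal single-causal-variant colocalization
engine (Wakefield approximate Bayes factors + posterior inclusion
probabilities), a multi-cohort simulator with ground-truth mechanisms for
benchmarking power and FDR, and probabilistic gene-set enrichment analysis
for downstream pathway interpretation.

## Worked example

Simulate a small benchmark dataset under known mechanisms, run the whole
pipeline, and fit the empirical-Bayes model:

```r
library(multipcg)

cfg <- sim_config(n_genes = 100, seed = 7)   # 3 cohorts of 500, 200 SNPs/gene
ds  <- simulate_dataset(cfg)
ds
#> <sim_dataset> 100 genes x 200 SNPs, 3 cohorts of 500 (seed 7)
#>
#>  M0  ME MEP  MP
#>  81   8   7   4

genes <- analyze_dataset(ds)   # QTL scans, weights, coloc, joint Wald test
fit   <- pcg_fit(genes)        # EB model selection + FDR control
fit
#> <pcg_fit> 100 genes | pi = 1.000 | h = (E 0.346, P 0.391, E+P 0.263)
#>   7 gene(s) rejected at Bayesian FDR 5%

tidy(fit) |>
  dplyr::filter(fdr_reject) |>
  dplyr::select(gene_id, gppc, lfdr, relevance_E, relevance_P)
#> # A tibble: 7 x 5
#>   gene_id   gppc       lfdr relevance_E relevance_P
#>   <chr>    <dbl>      <dbl>       <dbl>       <dbl>
#> 1 gene0008 1.000 0.00000280       0.606       0.640
#> 2 gene0024 1     0                0.183       1.000
#> 3 gene0029 0.855 0.145            0.639       0.433
#> 4 gene0039 0.827 0.173            0.492       0.531
#> 5 gene0073 1.000 0.0000501        0.901       0.312
#> 6 gene0080 1     0                0.306       0.997
#> 7 gene0099 0.990 0.0104           0.836       0.367
```

Each rejected gene is a PCG call at the 5% Bayesian FDR level; `gppc` is
the posterior probability that at least one product affects the trait, and
the relevance columns say which product carries the effect (values near 1
on one product and near 0 on the other indicate a clean single-product
mechanism). `glance(fit)` returns the estimated `pi` and mechanism
proportions; `autoplot(fit)` plots the relevance plane.

The benchmark wrapper scores power and realized FDR against ground truth,
for the multi-product fit and single-product comparators:

```r
report <- run_benchmark(list(cfg, sim_config(n_genes = 100, seed = 8)))
glance(report)
autoplot(report)
plot_discovery_curves(report, "E")
```

A thin command-line front end over the same functions is installed at
`inst/scripts/multipcg` (subcommands `run`, `simulate`, `coloc-lite`,
`gsea`; see the script header for flags).

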