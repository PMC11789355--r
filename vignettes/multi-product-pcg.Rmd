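---
title: "Implicating causal genes from multiple gene products: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implicating causal genes from multiple gene products: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(multipcg)
library(dplyr)
```

## The inference problem

A genome-wide association study (GWAS) locus rarely names its causal gene.
Transcriptome- and proteome-wide association studies (TWAS/PWAS) regress the
trait on genetically predicted expression (*E*) or protein abundance (*P*),
but a significant association can arise purely from linkage disequilibrium
(LD) between a molecular QTL and a distinct trait-causal variant — *LD
hitchhiking*. Colocalization analysis asks the complementary question —
do the molecular QTL and the GWAS signal share a causal variant? — and is
robust to hitchhiking but often underpowered.

`multipcg` combines both evidence types across **multiple gene products
simultaneously**. For each candidate gene it considers four mutually
exclusive mechanism models,

* $M_0$: no product affects the trait,
* $M_E$: only expression affects the trait,
* $M_P$: only protein abundance affects the trait,
* $M_{E+P}$: both do,

and reports

* the **gene probability of putative causality (GPPC)**
  $\Pr(M_0^c \mid \text{data})$, whose complement is a local false
  discovery rate (lfdr) suitable for Bayesian FDR control, and
* **gene-product relevance probabilities**, e.g.
  $\Pr(E \text{ affects } Y \mid \text{data}) =
  \Pr(M_E \mid \text{data}) + \Pr(M_{E+P} \mid \text{data})$.

## Structural model and instruments

The generative view is a structural equation model over genotypes $G$,
products $E, P$, latent confounding $U$, and trait $Y$:

$$
\begin{aligned}
E &= G\beta_E + \theta_E U + e_E \\
P &= G\beta_P + \theta_P U + e_P \\
Y &= G\beta_Y + \gamma E + \delta P + \theta_Y U + e_Y,
\end{aligned}
$$

with all phenotypes pre-centered. The targets of inference are whether
$\gamma \ne 0$ and/or $\delta \ne 0$ — a model-selection question, not an
effect-estimation one. Direct (pleiotropic) SNP effects $\beta_Y$ are not
estimated; the colocalization prior guards against them.

Because $E$ and $P$ are endogenous, the trait is regressed on genetic
instruments: predicted products $\hat E = G\hat\beta_e$,
$\hat P = G\hat\beta_p$ built from molecular-QTL cohorts that may be
disjoint from the GWAS cohort (multi-sample design). Fitting
$Y = \gamma \hat E + \delta \hat P + e$ without intercept yields a joint
$R^2$ that equals the squared canonical correlation between $Y$ and
$(\hat E, \hat P)$ — `joint_wald_individual()` asserts this identity, and
the tests verify it against `stats::cancor()`. The joint Wald statistic is
$W = n R^2 / (1 - R^2)$ on 2 degrees of freedom (1 if the instruments are
collinear; `rank_deficient` is set and the stronger product kept, with a
collinearity cut-off at $|\rho| > 0.999$).

With only GWAS summary statistics, `joint_wald_summary()` forms
$u = (w_E^\top z,\ w_P^\top z)$ with covariance
$\Sigma = [w^\top R w]$ from an LD matrix $R$ and computes
$W = u^\top \Sigma^{-1} u$. z-scores live on the standardized-genotype
scale, so allelic-scale weights are mapped with `standardize_weights()`
(per-SNP genotype standard deviations). A ridge of $10^{-8}\,\mathrm{tr}\,
\Sigma$ stabilizes near-singular cases. With in-sample LD, per-gene
results are nearly identical to the individual-level path (the acceptance
suite checks a correlation above 0.99 between the two GPPC vectors); a
mismatched reference panel will degrade this in practice.

### Instrument weights

Three weight builders are provided:

* `conditional_weights()` (pipeline default): forward stepwise conditional
  selection (entry at conditional $|z| > 3.9$, at most 5 SNPs), then joint
  least-squares effects — the standard conditional-analysis construction.
  Molecular traits routinely carry several independent cis signals;
  single-signal weights miss the secondary ones, and the missed signal then
  surfaces in the *other* product's instrument, biasing model selection
  toward $M_{E+P}$. In the pipeline both products are fit on the **union**
  of their selected SNPs, so shared-QTL signal leakage is carried by the
  instrument correlation, where the model can account for it.
* `build_weights(method = "top_snp")`: the single most significant QTL —
  the common choice for protein data.
* `build_weights(method = "pip_weighted")`: posterior-inclusion-probability
  weighted marginal effects, mirroring fine-mapping-based TWAS weights.

## Bayes factors for the mechanism models

Per gene, the instrument-level scores $z = (z_E, z_P)$ are modelled as
$z \sim N(\Lambda \phi, \Lambda)$ with
$\Lambda = \begin{bmatrix}1 & \rho\\ \rho & 1\end{bmatrix}$, $\rho$ the
instrument correlation. Each mechanism model places a normal prior on its
active coordinates of $\phi$, with variance averaged uniformly over
$\tau \in \{1, 2, 4, 8, 16, 32, 64, 128\}$; `model_log_bfs()` evaluates the
resulting Gaussian marginal-likelihood ratios in closed form. Two features
matter:

* **Correlation-aware single-product models.** Under $M_E$ the expected
  leakage into $z_P$ is $\rho\, \phi_E$; the model explains it rather than
  crediting it to $M_{E+P}$.
* **A small cross-product "leak" variance (default 2)** on the inactive
  coordinate of single-product models. Prediction weights are estimated
  with error, so even a purely expression-driven gene shows an apparent
  conditional protein association of a few $\chi^2$ units; without this
  term such genes are systematically absorbed by the joint model. The value
  2 matches the empirical size of this artifact at cohort sizes of a few
  hundred and is deliberately far below the signal prior scale.

At $\rho = 0$ and zero leak, the single-product Bayes factors reduce to the
scalar shrinkage Bayes factor `wald_to_log_bf()` (grid
$\{1, 2, 4, 8, 16\}$, the form used by single-trait predecessors), which is
also exposed as `gene_bayes_factors(method = "wald")`.

## Colocalization engine

A deliberately minimal single-causal-variant engine stands in for full
multi-SNP colocalization pipelines: Wakefield-style approximate Bayes
factors per SNP (`snp_log_abf()`, shrinkage grid $\{0.5, 0.8, 0.9\}$),
posterior inclusion probabilities under an at-most-one-causal-variant model
(`finemap_single_causal()`, flat per-SNP prior $1/(p+1)$ so the null
retains mass), and a gene-level colocalization probability
$1 - \prod_j (1 - \mathrm{pip}^{qtl}_j\, \mathrm{pip}^{gwas}_j)$
(`gene_coloc_prob()`). Externally computed gene-level colocalization
probabilities (e.g., from signal-cluster methods) can be supplied directly
through the evidence table, bypassing this module.

In the full pipeline, colocalization is evaluated over the molecular-QTL
candidate SNP set (the union of both products' conditional selections)
while every SNP keeps its genome-wide prior $1/(p+1)$. This approximates
signal-level colocalization: a strong unrelated GWAS signal elsewhere in
the region (e.g., a purely pleiotropic variant) cannot absorb the single-
causal posterior mass and mask a genuine overlap at the QTL, while chance
associations at null genes still fail to colocalize because the
genome-wide prior keeps their posterior mass small.

## Empirical-Bayes model selection

The composite prior of putative causality is
$\pi f(p_{\mathrm{coloc},E},\ p_{\mathrm{coloc},P})$ with the truncated
linear prior function (default): $f = c\cdot 1\{c \ge t\}$,
$c = \max(p_E, p_P)$, threshold $t = 0.05$; a step shape and a
$1-\prod(1-p)$ combination rule are alternatives. Zero colocalization on
every product always forces a zero prior — colocalization is treated as a
necessary condition for putative causality.

Two EMs are run across genes:

1. `estimate_pi()`: the mixture proportion $\pi$ in
   $L_i = (1 - \pi f_i) + \pi f_i\,\mathrm{BF}_i$. With gene-specific
   $f_i$ the M-step has no closed form, so it is solved by 1-D numerical
   optimization; the observed log-likelihood is non-decreasing and
   convergence is $|\Delta\pi| < 10^{-8}$ (at most 1000 iterations). Flat
   likelihoods return the initialization 0.5 with a warning; all-zero $f$
   returns 0 with a warning.
2. `em_estimate_h()`: the conditional mechanism proportions
   $h = (h_E, h_P, h_{E+P})$, $\sum h = 1$, by a standard finite-mixture
   EM over the non-null block with the composite priors held fixed
   (two-stage procedure; convergence $\|\Delta h\|_\infty < 10^{-8}$, at
   most 5000 iterations, genes accumulated in `gene_id` order for
   reproducibility). The default in `pcg_fit()` adds a weak symmetric
   Dirichlet pseudo-count of 1 (posterior mode): with only a few dozen
   informative genes per analysis the profile likelihood near the simplex
   corners is nearly flat, and the pseudo-count keeps estimates off the
   corners without materially moving interior solutions.
   `em_estimate_h()` itself defaults to the pure maximum-likelihood EM,
   which the tests verify against an exhaustive simplex grid search.

`pcg_fit()` then computes posterior model probabilities
$\Pr(M_m \mid \text{data}) \propto \pi f\, h_m\, \mathrm{BF}_m$ (null:
$1 - \pi f$), relevance probabilities by marginalization, and the GPPC. By
default the GPPC uses the estimated $h$ as mixture weights for the overall
Bayes factor, so that $\mathrm{GPPC} = 1 - \Pr(M_0 \mid \text{data})$
exactly and relevance probabilities can never exceed the GPPC;
`gppc_mixture = "uniform"` restores the two-stage variant in which the
GPPC uses the uniform $1/3$ mixture computed before the mechanism EM.
Rejections use the Bayesian FDR rule (`bayesian_fdr_control()`): sort
lfdrs, reject the largest prefix whose running mean stays at or below the
target, tie blocks all-or-none.

For more than two products the model space is all non-empty product
subsets; enumeration (`product_models()`) is supported for up to four
products and refused beyond that, where the $2^p$ growth makes exhaustive
model selection impractical.

## The simulator and what it emulates

`simulate_dataset()` generates the multi-cohort study conditions used for
benchmarking: per gene, three disjoint cohorts of 500 individuals
(expression, protein, GWAS), synthetic genotypes with minor-allele
frequencies uniform on $[0.05, 0.5]$ (independent SNPs by default; an
AR(1)-block mode adds LD for sensitivity checks), two eQTLs and two pQTLs
with exactly one shared variant, a distinct direct-effect GWAS SNP for
**every** gene (the stringent exclusion-restriction violation; a flag
disables it), all edge effects drawn $N(0, 0.6^2)$, residual variances 1,
a latent confounder with $N(0, 0.6^2)$ effects on $E$, $P$, and $Y$, and
causal mechanisms drawn from a multinomial over
$(M_0, M_E, M_P, M_{E+P})$ — default $(0.8, 0.1, 0.05, 0.05)$, i.e., about
20% causal genes. Under these conditions the mean realized expression
heritability per gene falls around 0.15–0.20, comparable to estimated
metabolite heritabilities.

What the synthetic genotypes do *not* emulate: real cis-region LD
structure, allele-frequency spectra, or overlapping cis-windows of
neighboring genes. Passing benchmarks therefore demonstrate the method's
operating characteristics under idealized linkage equilibrium (plus
optional block LD), not performance on real genotype panels.

`run_benchmark()` executes the full pipeline per dataset and scores
realized power and FDR against ground truth for the multi-product fit and
both single-product comparators, collects EM estimates, posterior-
probability strata by true mechanism, and cumulative true/false discovery
curves. It accepts `sim_config` objects and simulates datasets one at a
time, so memory stays at a single dataset. Default benchmark scale in the
package's own tests: 20 datasets of the primary mechanism setting plus 8
of each alternative setting, 300 genes each — small enough to run
routinely, large enough for stable averages.

```{r quick-run}
cfg <- sim_config(n_genes = 60, n_per_cohort = 300, snps_per_gene = 60,
                  seed = 1)
report <- run_benchmark(cfg)
glance(report)
```

## Gene-set enrichment from probabilistic labels

Across traits, per-gene probabilities aggregate as
$1 - \prod_i (1 - \mathrm{GPPC}_i)$ (`aggregate_gppc()`), the probability
of causality for at least one trait. `estimate_enrichment()` fits
$\Pr(\text{causal}_i) = \mathrm{logistic}(\alpha_0 + \alpha_1 d_i)$ with
set membership $d_i$, treating the aggregated probabilities as posterior
causal labels (soft-label logistic regression fit by iteratively
reweighted least squares; Wald confidence interval from the observed
information). Terms whose annotated genes all have zero probability are
excluded by `enrichment_scan()`; degenerate inputs (all probabilities 0 or
all 1) are flagged rather than estimated.

## Numerical conventions and degenerate inputs

* Probabilities are stored in linear space; Bayes factors in natural-log
  space throughout (`logsumexp`-style reductions; posterior arithmetic via
  stable log-odds updates).
* All regressions are intercept-free on pre-centered data; genotypes are
  column-centered before prediction.
* Ties: top-SNP selection breaks $|z|$ ties by lexicographic SNP id;
  FDR-boundary lfdr ties are included or excluded as a block.
* Monomorphic SNPs scan to effect 0 with infinite standard error and are
  never selected.
* Genes with evidence for only one product are dropped from the joint
  file-based analysis by default (`require_all_products = FALSE` keeps
  them).

## Known limitations

* The single-causal-variant colocalization stand-in splits posterior mass
  across allelic series (a gene with two equally strong eQTLs caps its
  colocalization probability well below 1), making the prior — and hence
  power — conservative relative to multi-SNP signal-cluster methods.
* Mechanism-proportion estimates are evidence-weighted: genes whose
  evidence survives the colocalization filter are not a random sample of
  causal genes (both-product genes are over-represented), which biases
  $\hat h$ slightly toward $M_{E+P}$ at small gene counts.
* The summary-statistics path assumes the LD panel matches the GWAS
  sample; mismatch consequences are not modelled.
* Causal effect sizes $\gamma, \delta$ are tested, never estimated with
  confidence intervals, and tissue/cell-type resolution is out of scope.
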