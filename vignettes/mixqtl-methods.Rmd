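---
title: "Combining total and allele-specific counts: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining total and allele-specific counts: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixqtl)
```

This vignette documents the statistical machinery of `mixqtl`: the
log-linear count model and its two derived regressions, the
meta-analytic single-variant test, the two-step variance scaling behind
multi-SNP fine-mapping and prediction, the generative simulator, and the
numerical and design decisions that were genuinely open.

## 1. The count model and its linearization

Phased RNA-seq gives, per gene and individual $i$, a total read count
$Y_i^{\text{total}}$ and haplotype-assignable allele-specific counts
$Y_i^{(1)\text{obs}}, Y_i^{(2)\text{obs}}$ (the reads overlapping at
least one heterozygous site). The multiplicative cis-effect model for
the (unobserved) haplotypic counts is

$$Y_i^h = L_i\,\theta_{0,i}\,e^{\beta X_i^h}\,e^{\epsilon_i^h},\qquad h = 1,2,$$

with library size $L_i$, baseline abundance $\theta_{0,i}$, phased
dosages $X_i^h \in \{0,1\}$ and allelic fold change
$\mathrm{aFC} = e^\beta$. Taking logs and assuming weak effects gives
two approximately independent equations:

* **Allelic imbalance.**
  $\log(Y_i^{(1)\text{obs}}/Y_i^{(2)\text{obs}}) = (X_i^1 - X_i^2)\beta + \epsilon_i^{\text{asc}}$,
  $\ \epsilon_i^{\text{asc}} \sim N\!\big(0,\ \sigma^2(1/Y_i^{(1)\text{obs}} + 1/Y_i^{(2)\text{obs}})\big)$.
  Everything individual-level — library size, baseline abundance, the
  allele-specific readout fraction, covariates — cancels in the ratio,
  which is why this regression has no intercept and is never
  covariate-adjusted.
* **Total read count.**
  $\log(Y_i^{\text{total}}/2L_i) = \mu_0 + \tfrac{X_i^1 + X_i^2}{2}\beta + \tilde z_i$,
  $\ \tilde z_i \sim N(0, \tilde\sigma_0^2)$, where $\tilde z$ merges the
  baseline-abundance variation and the count noise into one
  homoskedastic term.

The inverse-count error variances encode the assumption that the count
variance scales *linearly* with the count — over-dispersion enters as
the proportionality constant $\sigma^2$, not as a quadratic term. This
assumption matters: it justifies the weights, and the simulator (see
§5) respects it.

## 2. Single-variant test (`run_cis_scan`)

Per variant, `fit_trc()` is OLS with intercept on the covariate-adjusted
total-count response (p from $t_{n-2}$) and `fit_asc()` is weighted
least squares through the origin with weights
$w_i = (1/Y^{(1)}_i + 1/Y^{(2)}_i)^{-1}$ after capping
($\hat\beta = \sum w x y / \sum w x^2$,
$\hat\sigma^2 = \sum w r^2/(n-1)$, p from $t_{n-1}$). The two estimates
are combined by fixed-effect inverse-variance meta-analysis with a
normal p-value — the standard treatment of independent studies. The
component p-values use $t$ distributions because each component
estimates its own error variance; the paperless choice of $t$ versus
normal is immaterial at the sample sizes involved but is the
conservative option. When the allelic-imbalance fit is unavailable
(fewer than `min_asc_samples_for_meta = 15` usable samples, or no
heterozygous carriers) the scan reports the total-count component with
`method = "trc"`, so every gene is testable regardless of
allele-specific coverage.

Weight capping limits each weight to at most $K = \min(10, n/10)$ times
the smallest (floored at $K = 1$ for degenerate tiny studies),
preventing a few very high-count samples from dominating
$\hat\beta^{\text{asc}}$.

### Filters

`filter_config()` carries the production defaults for real alignments: a
sample enters the imbalance regression only with more than 15 reads on
*both* haplotypes, and counts above 1000 are discarded as likely
alignment artifacts; zero total counts are imputed to 1 before the log;
an optional gene-level screen asks for 15 samples with ≥ 50
allele-specific reads per haplotype and 500 samples with total ≥ 100.
`sim_filter_config()` differs in exactly one way: the artifact rule is
disabled, because simulated reads contain no alignment artifacts and at
high expression the rule would censor precisely the high-count
alternative-haplotype carriers, biasing $\hat\beta^{\text{asc}}$ toward
zero (we measured ~35% attenuation at aFC = 2, θ = 5×10⁻⁵ with the rule
left on).

### Covariates

`adjust_covariates()` uses two joint OLS stages: regress the total-count
response on all covariates, keep those with two-sided $p < 0.05$, refit
on the kept set and return residuals (the centered response when
nothing is kept). Selection uses the joint fit rather than marginal
screens because the covariates are regressed out jointly downstream.

## 3. Two-step variance scaling (`build_augmented`)

Multi-SNP solvers expect one homoskedastic linear model
$y = X\beta + e$. Step one estimates the two error scales by REML,
treating the cis genetic effects as random
($u \sim N(0, \sigma_g^2 K)$ with $K = XX^\top/p$): for the
total-count block with unit weights and a fixed intercept, for the
imbalance block after pre-whitening rows by $\sqrt{w_i}$ with no
intercept. `estimate_variance_components()` eigendecomposes the
projected kernel once (via the $p \times p$ cross-product, so cost is
$O(np^2)$) and maximizes the REML log-likelihood over the single ratio
$\delta = \sigma_e^2/\sigma_g^2$ on a 64-point grid over
$\log\delta \in [-10, 10]$ followed by Brent refinement in the best
bracket — the grid guards against local optima, the bounds cover
variance ratios from $e^{-10}$ to $e^{10}$, and the upper boundary
(no detectable genetic variance) is a routine outcome under the null
rather than an error.

Step two stacks

* the total-count block, centered (response and dosage columns) and
  divided by $\hat{\tilde\sigma}_0$, with dosage coding $(X^1+X^2)/2$;
* the imbalance block, each row multiplied by
  $\sqrt{w_i}/\hat\sigma$, with coding $X^1 - X^2$ and no centering.

The same $\beta$ (per-allele log fold change) solves both blocks, each
row has approximately unit error variance, and the blocks are
approximately independent — so ordinary solvers apply to the stacked
rows. The scaling factor is $\sqrt{w}/\sigma$, the unique choice that
standardizes an $N(0, \sigma^2/w)$ error to unit variance. On
single-variant data, OLS on the stacked rows reproduces the
meta-analysis z-score (we verify agreement within a fraction of a
percent); the augmented dataset is the multi-SNP generalization of the
same combination.

## 4. Fine-mapping (`mixfine`) and prediction (`mixpred`)

### Sum of single effects

`ibss_fit()` is a minimal, deterministic implementation of the
sum-of-single-effects variational scheme: $L$ (default 10) effects, each
constrained to one nonzero coordinate with a $N(0, \sigma_{0l}^2)$
prior and uniform inclusion prior over variants. Each sweep
residualizes the other effects and solves the single-effect problem in
closed form (per-variant Bayes factors from the univariate summaries);
iteration stops when the variational objective (ELBO) changes by less
than `tol = 1e-3`. The residual variance is re-estimated each sweep;
each effect's prior variance is optimized by bounded one-dimensional
search of the single-effect marginal likelihood and set to zero when a
null prior fits as well — such effects, and effects whose inclusion
weights are *maximally diffuse* (participation ratio
$1/\sum_j \alpha_j^2$ above $\max(2, p/2)$, i.e. mass spread over at
least half the variants), are pruned before PIPs
($\mathrm{PIP}_j = 1 - \prod_l (1-\alpha_{lj})$) and credible sets are
formed. Without the diffuse-effect pruning, near-null effects each leak
$\sim 1/p$ inclusion mass and inflate every variant's PIP; with it, a
duplicated null column leaves other variants' PIPs unchanged to within
$10^{-6}$, which we test.

Credible sets take the minimal prefix of variants (sorted by inclusion
weight, ties by index) reaching 95% cumulative mass and are discarded
when the minimum pairwise absolute correlation of member columns falls
below 0.5 — the purity convention of the reference solvers, whose
published defaults ($L = 10$, coverage 0.95, purity 0.5) we adopt since
no other values are prescribed. `mixfine()` runs the solver on the full
augmented data, `trcfine()` on the total-count block only; a different
solver with the same `(y, X, cfg)` signature can be plugged in through
the `solver` argument.

### Elastic net

`fit_mixpred()` delegates the penalty path to glmnet (mixing parameter
0.5 by default, the transcriptome-prediction convention), run without
intercept or internal standardization — the augmented rows are already
centered and scaled, and the two coding schemes must share one
coefficient vector. The penalty is chosen by internal k-fold
cross-validation minimizing squared error *on total-count rows only*:
the deployable prediction target is $\log(Y^{\text{total}}/2L)$, so
model selection should target that scale, while imbalance rows of the
held-in samples still inform each fold's fit. Folds are formed over
samples so no held-out sample contributes rows of either block.
Predictions are $\hat y_i = \hat\mu + \sum_j \tfrac{X^1_{ij}+X^2_{ij}}{2}\hat\beta_j$,
with the intercept restoring the training-block centering.
`crossval_evaluate()` implements the inverted k-fold convention used in
the original evaluation — train on *one* fold, test on the remaining
$k-1$ — so larger $k$ probes smaller training sets; the simulation
harness `prediction_suite()` instead uses the 4/5-train, 1/5-test split
with each split repeated twice.

## 5. The simulator

`simulate_dataset()` composes three steps, mirroring how
haplotype-resolved counts arise:

1. **Gene-body configuration.** The number of polymorphic readout sites
   is Poisson (mean 10), positions uniform on a 2,000 bp gene body,
   per-site allele frequency uniform on $[0.05, 0.3]$; each individual's
   haplotype alleles are independent Bernoulli draws, so a site is
   heterozygous with probability $2f(1-f)$.
2. **Haplotypic counts.** Library sizes are negative binomial with mean
   94 million (matching large bulk RNA-seq cohorts); the baseline
   abundance is $\theta_{0,i} = 2\theta B_i$ with
   $B_i \sim \mathrm{Beta}(c, c)$, $c = 20$ — a Beta-distributed
   abundance with mean $\theta$ and ≈ 0.16 sd on the log scale. (A Beta
   parameterized directly by mean $5\times10^{-5}$ and a small
   concentration would be a degenerate, near-zero-inflated baseline —
   no expressed gene looks like that.) Haplotypic counts are negative
   binomial with $\mathrm{Var} = \phi\,\mathrm{E}$ (NB1; default
   $\phi = 1.5$). The NB1 choice is deliberate: the model's weighting
   assumes count variance proportional to the count, and a fixed-size
   NB2 at these expression levels (thousands of reads per haplotype)
   would instead give variance hundreds of times the mean, violating
   the very regime the method is built for.
3. **Allele-specific readout.** Each read starts uniformly on the gene
   body and is allele-specific iff it overlaps a heterozygous site. The
   per-read probability is the exact length of the union of het-site
   windows divided by the number of possible starts, and the
   allele-specific count is a binomial thinning of the haplotypic count
   with that probability — distributionally identical to placing each
   read, at $O(1)$ cost per sample. The observed total is
   $Y^1 + Y^2$ regardless of het sites.

**Effect sizes.** With `aFC` given, $\beta = \log(\mathrm{aFC})$. With a
target heritability `h2`, effects are drawn $N(0,1)$ and rescaled so the
variance of the average-dosage score is $h^2/(1-h^2)$ times the
non-genetic log-expression variance
$\mathrm{Var}(\log\theta_0) + \phi/(2L\theta)$ — i.e. $h^2$ is the
fraction of log total-count variance explained by the causal variants,
including the count-noise floor. We verify in simulation that the
realized regression $R^2$ matches the target.

**Linkage.** Independent sites are the default. `ld_rho` switches to
haplotypes generated by thresholding an AR(1) latent Gaussian process
(lag-one correlation `ld_rho`) at the per-site frequency — a *synthetic*
stand-in for a reference haplotype panel, giving LD that decays with
variant distance (lag-1 dosage correlation ≈ 0.6 at
$\rho = 0.9$). An external phased panel can be supplied via `ld_panel`
instead. The fine-mapping and prediction suites default to
`ld_rho = 0.9`: linkage is what spreads inclusion mass across
credible-set members, and with fully independent variants a strong
single causal signal pins its PIP at 1, leaving intermediate PIP bins
populated only by algorithmic false positives — unrepresentative of
panel-based evaluation.

**What the simulator does not emulate.** Reference-mapping bias and
genotyping error in allele assignment (so no artifact-outlier
generation), paired-end read geometry, multi-gene structure, trans
effects, and real LD beyond the AR(1)/panel approximations. Passing the
property suite therefore demonstrates correctness of the estimators
under the model's own assumptions plus moderate overdispersion and
readout thinning — not robustness to alignment artifacts, which the
production filters exist to handle.

## 6. Evaluation harness and problem sizes

`type1_power_suite()` reports rejection rates with Wilson 95% intervals
per grid cell (the default grid is a reduced version of the full
single-SNP design: $n \in \{100, 500\}$, $\theta \in \{5\times10^{-5},
10^{-6}\}$, aFC $\in \{1, 1.25, 2\}$); `finemap_suite()` reports
detections at PIP > 0.5, credible-set size/coverage and pooled PIPs for
calibration; `prediction_suite()` reports held-out Pearson r per split.
All suites derive per-replicate seeds from one master seed and are
exactly reproducible.

The shipped acceptance checks use: 200 replicates for null calibration
(n = 500, θ = 5×10⁻⁵) and for power ordering (n = 300, aFC = 1.5); 200
replicates per aFC ∈ {1.25, 2} for fold-change recovery (median within
5%); 50 synthetic datasets at n = 1000 for variance-component recovery
(median error within 20%); 100 signal + 20 null replicates with 200
linked variants for fine-mapping calibration and dominance; and 50
replicates × 2 splits for prediction (mean held-out r within 0.15 of
$\sqrt{h^2}$, combined ≥ total-only). These sizes keep the whole suite
in the low minutes on one core while leaving the directional
comparisons statistically meaningful.

## 7. Numerical choices, degenerate inputs, limitations

* Zero-variance (monomorphic) variants yield `NA` association results;
  zero-variance columns in the single-effect regression receive Bayes
  factor 1 (prior-proportional inclusion mass).
* Missing genotypes drop the affected samples for that variant only; no
  imputation is performed.
* Ties in credible-set construction break by variant index;
  identical duplicate sets from different effects are reported once.
* The REML ratio search is bounded at $e^{\pm 10}$; a lower-boundary
  fit ($\sigma_e^2 \to 0$, i.e. a noiseless response) is flagged with a
  warning, an upper-boundary fit is reported silently as
  "no genetic variance".
* `cap_weights` floors the cap at $K = 1$ when $n < 10$, equalizing all
  weights, a regime real studies never reach.
* The linearization is a weak-effect approximation: for large effects
  (aFC ≳ 2) the total-count slope overestimates $|\beta|$ by several
  percent (concavity of $\log(1 + e^\beta)/2$), partially offset in the
  meta-analysis by the unbiased imbalance component. Read-level methods
  remain preferable for very small samples.
* PIP calibration is assessed against bin midpoints; the bottom bin is
  intrinsically conservative (most null variants sit far below the
  0.05 midpoint), which the ≥ 8/10-bins acceptance rule absorbs.
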