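---
title: "Bayesian risk-index variable selection for rare and common variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian risk-index variable selection for rare and common variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Single-variant association tests lose essentially all power for rare
variants: with a minor allele frequency (MAF) of a few per ten thousand,
a cohort of one or two thousand people carries the allele a handful of
times. Burden-style methods regain power by collapsing rare variants into
a per-individual score, but a plain region-level burden test cannot say
*which* variants drive an association, and it treats common variants as a
separate problem. `rvbvs` frames the question as sparse variable selection
over all variants of a region at once, so that rare and common variants
compete in the same multivariate model and each receives its own evidence
measure.

## Model

For $n$ unrelated individuals with quantitative trait
$Y = (Y_1,\dots,Y_n)^\top$ and additive genotype dosages
$X_{ij} \in \{0,1,2\}$ (minor-allele counts, columns re-oriented so the
coded allele is always the minor one) at $p$ variants,

$$ Y = \beta_0 + \sum_g G_g \beta_g + \varepsilon,\qquad
   \varepsilon \sim N(0, \sigma^2 I_n). $$

A MAF threshold partitions the variants into $G$ groups: every common
variant ($\mathrm{MAF} \ge$ threshold) is its own group, and all rare
variants of a region form one group. A binary indicator vector
$\gamma \in \{0,1\}^p$ selects variants; the **risk-index score** of group
$g$ is $G_g = X_g \gamma_g$, the per-individual sum of dosages over the
*included* rare variants of the group (for a common singleton group,
simply that variant's dosage column). The model dimension is therefore
the number of *active groups*, not the number of included variants — that
is what makes extreme-rare variants estimable at all.

Two ingredients give a posterior over models:

* **Plug-in marginal likelihood.** $p(Y\mid\gamma)$ is approximated by the
  Gaussian likelihood at the maximum-likelihood estimates of
  $(\beta_0, \beta, \sigma^2)$ for that model: an ordinary least-squares
  fit of $Y$ on the intercept plus the active risk-index columns, with
  $\hat\sigma^2 = \mathrm{RSS}/n$. This is deliberately *not* a true
  integrated marginal likelihood and carries no dimensionality penalty of
  its own; all sparsity comes from the prior. The consequences are
  discussed under *Known behaviour* below.
* **Bernoulli model-space prior.**
  $p(\gamma) = \prod_j \pi^{\gamma_j} (1-\pi)^{1-\gamma_j}$ with prior
  inclusion probability (PIP) $\pi$. The default $\pi = 0.1$ expects one
  variant in ten included; $\pi = 0.5$ would be uniform over the
  $2^p$ models.

The object of inference is the **marginal posterior probability** (MPP)
of each variant: the posterior mass of all models that include it.

## Posterior exploration

The posterior $p(\gamma\mid Y) \propto p(\gamma)\,p(Y\mid\gamma)$ is
explored by Metropolis–Hastings with a single uniform bit-flip proposal.
The kernel is symmetric, so the Hastings ratio is exactly 1 and acceptance
is $\min\{1, \exp(\Delta \log\text{score})\}$; compound add/remove/swap
moves are a possible extension but would complicate the proposal ratio for
no demonstrated benefit at region scale. Chains start from the empty model
(a `random_start` option draws the start from the prior instead, for
stability checks across starting points). The default protocol discards
5,000 burn-in iterations and then keeps one state in 10 until 5,000 draws
are retained — $5000 + 5000 \times 10 = 55{,}000$ iterations — and the MPP
estimate is the fraction of retained draws including the variant.

Internally each proposal is scored in $O(m^2)$ using precomputed centred
cross-products ($X^\top X$, $X^\top y$, $y^\top y$) rather than refitting
on the $n \times m$ design; `score_state()` computes the same quantity by
an explicit least-squares fit, and the two routes are tested against each
other. Rank-deficient designs (e.g. duplicated rare columns) are solved by
pseudo-inverse; the residual sum of squares, and hence the score, is
unaffected. A variance floor of $10^{-12}\,\mathrm{var}(Y)$ keeps the
log-likelihood finite when a design with very few carriers interpolates
the phenotype.

For $p \le 20$, `enumerate_exact_posterior()` computes the posterior over
all $2^p$ models exactly; the package's central correctness test holds the
chain's MPPs to within 0.02 of this oracle at the default chain length
($n = 300$, $p = 10$, three seeds).

## Decision rule

Selection is two-staged, both comparisons strict:

1. **PIP screen** — a variant is *selected* when its MPP exceeds $\pi$.
2. **Permutation rule** — a paired chain with identical settings (but an
   independent seed) runs on a randomly permuted phenotype $Y^*$; its MPPs
   are per-variant *empirical* null thresholds. A selected variant is a
   *true positive* when its MPP also exceeds its empirical MPP.

One fixed permutation per analysis is the default. The alternative
reading — re-permuting the phenotype at every MCMC iteration — would make
the null chain target an iteration-varying distribution with no stated
stationary law, so it is not implemented; instead `n_permutations` lets
the empirical MPPs be averaged over several independent permutation
replicates. Each variant is compared to *its own* null MPP (the reported
per-variant empirical thresholds); a family-wise option
(`family_wise_null = TRUE`) compares every variant to the maximum null
MPP instead and is off by default.

Because any rare/common split is arbitrary, `maf_sweep()` repeats the
whole paired analysis over a grid of thresholds (default
$\{0.05, 0.04, 0.03, 0.02, 0.01\}$ — definitions of rarity starting at
5%), averages each variant's MPP and empirical MPP arithmetically across
thresholds, and applies the rule to the averages. Empirical MPPs are
averaged the same way as observed ones, for symmetry; the report header
records the grid. Convergence of every observed chain is monitored by a
Geweke z-test on the retained log-score trace (a scalar functional;
per-component indicator traces are binary and ill-suited): means of the
first 10% and last 50% windows compared with spectral variance estimated
by non-overlapping batch means, about $\sqrt{\text{window length}}$
batches. A constant trace is reported as converged with $z = 0$.

## Data handling

Genotypes come from a VCF (GT field, biallelic SNVs; multiallelic records
skipped with a warning; `./.` is missing) or a headered TSV matrix;
phenotypes from a TSV joined on sample ID. Variant IDs use the
`<chrom>_<pos>` convention with 1-based positions. Filtering is
complete-case: individuals with any missing genotype or phenotype are
removed, then minor-allele counts are recomputed and monomorphic variants
and singletons (MAC $\le$ 1; the cutoff `min_minor_allele_count` is
exposed, set 0 to disable) are dropped, then MAFs are recomputed on what
remains — so MAF reflects the analysed individuals, not the raw file. No
imputation is attempted; the model has no covariates. A natural-log
transform (`log_transform()`) is available for right-skewed traits; the
base is immaterial downstream because the fit is affine-equivariant in
$Y$.

## Synthetic data

`simulation_scenario()` / `simulate_dataset()` generate the kind of data
the method assumes: independent Hardy–Weinberg dosages
$X_{ij} \sim \mathrm{Binomial}(2, \mathrm{maf}_j)$, a linear trait
$Y_i = \beta_0 + \sum_{j\,\text{causal}} \beta_j X_{ij} + \varepsilon_i$
with Gaussian noise, optional uniform genotype missingness. The default
scenario mirrors a single-gene sequencing panel after QC — 1,851
individuals, 85 variants — with MAFs on a deterministic log-spaced grid
over $[3\times 10^{-4}, 0.35]$, spanning extreme-rare (singleton-prone,
so the filters are exercised) to common. Effect sizes are parameterised in
units of the noise SD so scenarios are scale-free. The grid is
deliberately seed-independent: replicates differ in genotypes and noise,
never in spectrum.

What the generator does *not* emulate: linkage disequilibrium (the model
itself assumes independent variants and no interactions), population
structure or relatedness, covariates, and binary traits. Passing tests on
this generator therefore demonstrate correctness of the machinery and
calibration under the model's own assumptions, not robustness to LD or
confounding in real cohorts.

## Problem sizes used in the shipped checks

The package's test-and-verification suite was sized for a desk run:
chain/oracle agreement uses $n = 300$, $p = 10$ with three full-length
chains; recovery and null calibration use 20 replicates each of
$n = 1000$ with 22 variants (one common causal, MAF 0.3 at 0.3 SD; one
rare causal, MAF 0.005 at 1 SD; 20 nulls on the log-spaced spectrum) at
the default 55,000-iteration protocol; Geweke calibration uses 100
stationary traces of length 5,000.

## Known behaviour and limitations

* **The PIP screen is permissive for common variants by construction.**
  Appending a free column never increases the residual sum of squares, so
  under the plug-in likelihood the conditional posterior odds of including
  a variant that owns its own group are at least $\pi/(1-\pi)$ in *every*
  configuration — hence a common variant's exact MPP exceeds $\pi$ with
  probability one, even for pure noise. Stage 1 therefore does no real
  filtering for common variants; the permutation stage carries the burden
  of separating them from noise, and with a single permutation a null
  common variant still passes it about half the time (observed and null
  MPPs are exchangeable under the null). Practical consequences: expect
  false positives among common variants at roughly half their count when
  the region is null; rank by MPP rather than treating the true-positive
  flag as a calibrated test; consider `family_wise_null = TRUE` or
  `n_permutations > 1` when stricter control is wanted. Rare variants
  inside a shared group do not get the free-column boost (inclusion only
  perturbs an existing burden column), so the rule is markedly better
  behaved for them — which is the method's focus.
* The plug-in approximation is not a marginal likelihood; no
  $g$-prior/BIC-type penalty is added on top of it, faithfully keeping
  all sparsity in $\pi$.
* MPP magnitudes are sensitive to $\pi$ (smaller $\pi$, smaller MPPs);
  rankings are much less so. The default $\pi = 0.1$ is a sparsity
  choice, not an estimate.
* Exact enumeration is exponential in $p$ and guarded at $p \le 20$; the
  sampler is intended for region-scale panels (tens of variants), not
  genome-wide scans.
* The Geweke flag at $|z| < 1.96$ is a nominal-5% test: on perfectly
  stationary traces it still fails about 5% of the time, and the
  batch-means variance estimate adds a little heaviness to the tails.
  Treat it as a screen, not a proof of convergence.

## A worked example

```{r, eval = FALSE}
library(rvbvs)

sc <- simulation_scenario(
  n = 1000,
  maf_spectrum = c(exp(seq(log(3e-4), log(0.35), length.out = 20)),
                   0.3, 0.005),
  causal_index = c(21L, 22L), effect_sizes = c(0.3, 1.0), seed = 42)
d  <- simulate_dataset(sc)
fl <- filter_data(d$genotypes, d$phenotype)

report <- maf_sweep(fl$phenotype, fl$genotypes,
                    sampler_config(seed = 7),
                    thresholds = c(0.05, 0.03, 0.01))
head(rank_report(report))
plot_mpp_profile(report)
```

The two causal variants (`1_1021000`, `1_1022000`) should head the
ranking with averaged MPPs far above both $\pi = 0.1$ and their empirical
thresholds; a handful of common null variants will sit just above
$\pi$ — the behaviour described under *Known behaviour* — and the
per-threshold profile plot shows the causal signals as constant peaks
across rarity definitions.
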