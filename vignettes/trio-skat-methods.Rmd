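---
title: "Transmission-conditioned region tests in trios: model, numerics, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission-conditioned region tests in trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioskat)
```

## The model

trioskat tests whether a genomic region (a gene, a set of variants) is
associated with a quantitative or dichotomous trait using parent–offspring
trios. For trio $i$ with offspring trait $Y_i$, covariates $C_i$ and offspring
dosages $X_{i1},\dots,X_{im}$ over the $m$ region variants, the generalized
linear mixed model is

$$h(\mu_i) = C_i\alpha + X_i\beta,$$

with $h$ the identity (continuous traits) or logit (dichotomous) link. The
per-variant effects $\beta_j$ are treated as independent random effects with
mean zero and variance $w_j^2\tau$; "no genetic effect" is the variance
component null $H_0\colon\tau = 0$. The score statistic for this null is the
quadratic form

$$Q_\rho = (Y-\hat\mu_0)^\top\,
  (X - E[X\mid X_p])\, W R_\rho W\, (X - E[X\mid X_p])^\top
  (Y-\hat\mu_0),$$

where $X_p$ are the parental genotypes, $W=\mathrm{diag}(w_j)$, and
$R_\rho=(1-\rho)I+\rho 1 1^\top$ is an exchangeable effect-correlation
matrix. $\rho=0$ gives the variance-component kernel (the SKAT form, a
weighted sum of squared per-variant score sums); $\rho=1$ collapses the
weighted scores into one squared sum, the FBAT-style burden statistic.
Intermediate $\rho$ interpolates linearly between the two.

The defining feature of the family-based version is the centering
$X - E[X\mid X_p]$: each offspring dosage is centred at its Mendelian
expectation given the parents, $E[X_{ij}\mid X_p]=(g_{f,ij}+g_{m,ij})/2$.
Only the randomness of allelic transmission is left in the statistic, so the
null distribution is valid conditional on parental genotypes. This is the
transmission-disequilibrium principle: confounding that operates through
ancestry (population stratification) shifts parental genotype frequencies
and trait means, but cannot bias which allele a heterozygous parent
transmits. The package's stratification tests exercise exactly this
property.

## Weights

$w_j = \mathrm{Beta}(\hat f_j; a, b)$ is the Beta *density* evaluated at the
variant's minor-allele frequency $\hat f_j$, estimated from the parents only
(coded-allele count over non-missing parental alleles). The default
$(a,b)=(1,25)$ is the convention in the kernel-association literature: it
concentrates essentially all weight on rare variants ($w \approx 23$ at
$f = 0.003$ versus $w \approx 0.005$ at $f = 0.3$). $(1,1)$ gives an
unweighted test. Both are exposed everywhere (`weights_beta`, CLI flag
`--weights-beta`).

## Null distribution and p-values

Conditional on parents and trait, $Q_\rho$ converges to a mixture
$\sum_j \lambda_j \chi^2_{1,j}$ whose weights are the eigenvalues of
$W R_\rho W V$, $V=\mathrm{Cov}\big((X-E[X\mid X_p])^\top(Y-\hat\mu_0)\,\big|\,X_p,Y\big)$.
Two estimators of $V$ are provided:

* **mendelian** (default): transmissions at distinct variants are
  independent given parents, so $V=\sum_i r_i^2 v_i$ with $v_i$ diagonal and
  $\mathrm{Var}(X_{ij}\mid X_p) = (\mathbb{1}[g_f=1]+\mathbb{1}[g_m=1])/4$.
  Exact for variants in linkage equilibrium — which is how the simulator
  generates them.
* **empirical**: $V=\sum_i r_i^2 s_i s_i^\top$ from observed score outer
  products, the estimator to use for real, linked variants.

Eigenvalues are clipped at zero and truncated below $10^{-10}\lambda_{max}$.

Tail probabilities of the mixture are computed by numerically inverting its
characteristic function: the inversion integral is evaluated by adaptive
quadrature up to the first zero of the oscillating phase and then over
successive half-period segments whose alternating contributions are summed
with repeated averaging. This reproduces $\chi^2$ closed forms to near
machine precision across the testable range. If the quadrature fails its
accuracy contract, the p-value falls back to Liu-type moment matching (the
first cumulants of the mixture matched to a noncentral $\chi^2$ surrogate);
the route taken is recorded in every result (`p_method`). Moment matching is
exact for a single eigenvalue and accurate to a few percent in the moderate
tail otherwise.

Degenerate cases are defined rather than errored: all-zero residuals or an
all-homozygous region give $\lambda = 0$ and $p = 1$; an empty variant
stratum yields a structured "untestable" result.

## Input handling choices

* Variants are recoded so the coded allele is the minor allele *in the
  parental sample*; a tie at frequency 0.5 keeps the ALT (VCF) or "1"
  (dosage-matrix) allele — deterministic and format-native.
* Trio extraction groups offspring by (father, mother) pair and draws one
  genotyped offspring per pair uniformly at random (seeded). The draw is
  made among genotype-complete offspring, not before the completeness check,
  so a family is never lost to an unlucky draw; half-siblings form distinct
  pairs. Each pair contributes at most one trio, which keeps transmissions
  independent across trios given parents.
* Mendelian-inconsistent offspring genotypes (impossible given the parents)
  are set to missing and counted; missing trio-variant cells contribute zero
  to both the score and its variance rather than dropping the trio.
* BED intervals are 0-based half-open and matched against 1-based VCF
  positions as `start < pos <= end`, centralized in one resolver.
* Monomorphic-in-parents variants carry no transmission information and are
  excluded from both MAF strata; the rare/common boundary (default 0.05) is
  inclusive on the rare side.

## The simulator

`sim_config()` / `generate_cohort()` emulate a blood-pressure-style trio
study with known truth:

* **Cohort size**: 93 trios, 30 variants per region — the scale of a
  realistic trio study assembled from extended pedigrees.
* **MAF spectrum**: 80% of variants draw from a density $\propto 1/f$ on
  $(1/(4N), 0.05]$, a neutral-spectrum caricature producing realistic
  rare-variant sparsity; the rest are uniform on $(0.05, 0.5]$. Parents are
  Hardy–Weinberg draws; offspring follow Mendelian transmission, so the
  generated data contain zero Mendelian errors by construction.
* **Traits**: `trait1` and `trait2` stand in for two highly correlated
  pressure phenotypes — identical causal sets, trait2 effects $0.8\times$
  trait1's, residual correlation 0.6; `q1` is pure noise, the type-I-error
  trait. Causal effect magnitudes follow $|\beta_j| = c\,|\log_{10}\hat f_j|$
  (rarer variants hit harder) or a constant, with `direction_mix` the exact
  proportion of positive signs among causal variants (0.5 = balanced
  mixed-sign architecture favouring the variance-component test, 1 =
  same-direction architecture favouring the burden test).
* **Stratification mode**: two subpopulations with Balding–Nichols
  frequency divergence (parameter $F_{st}$) and a trait mean offset; both
  parents of a trio share a subpopulation. This creates genuine
  ancestry–trait confounding while the region stays causally null.

What the simulator does **not** emulate: linkage disequilibrium (variants
are independent — matching the default covariance estimator), genotyping
error, de-novo mutation, X-linked inheritance, and real pedigree depth
(only trios are generated). Passing tests therefore demonstrate correctness
of the transmission-conditioned machinery under clean Mendelian data, not
robustness to artefacts of real sequencing.

## Study designs shipped with the package

The replicate designs mirror a simulation study in which genotypes are
shared across replicates and phenotype noise is redrawn
(`regenerate = "phenotypes"`); fully fresh cohorts per replicate are one
switch away (`"cohort"`, the default for type-I-error estimation, where the
spectrum itself is part of the randomness being averaged over). The scenario
grid crosses trait (trait1/trait2) $\times$ method (skat/burden) $\times$
stratum (rare/common/all) — 12 cells — optionally $\times$ causal-signal
proportion $\{0.10, 0.25, 0.50\}$ for 36. Signal dilution keeps every causal
variant and adds $k=\mathrm{round}(n_c(1-\pi)/\pi)$ noncausal ones; genes
used in diluted designs must hold at least one causal rare and one causal
common variant.

Power-ordering studies use rare-only regions with MAF floor 0.01, half the
variants causal, and constant effect magnitude 1.2 trait-SD per allele,
pooled over four independent gene architectures: large enough that the
favoured test shows clear power at 93 trios, small enough that neither
saturates — so the SKAT-vs-burden gap is resolvable above Monte-Carlo noise
in 500 replicates, and not hostage to a single random draw of causal signs. The stratification study uses
common variants ($F_{st}=0.1$, trait offset of 1 SD between subpopulations):
allele-frequency confounding is classically a common-variant phenomenon, and
a calibrated baseline is needed for inflation — the quantity stratification
would induce — to be attributable to stratification alone. Problem sizes
throughout (2000 null replicates for calibration, 500 for power contrasts,
$10^4$ draws for distributional checks) were chosen so binomial/Monte-Carlo
noise is well below the effects being asserted.

## The GEE power comparison

Rejection counts $y_{ij}\sim\mathrm{Binomial}(n_{\text{reps}}, p_{ij})$ for
scenario $j$ of gene $i$ are compared with the marginal model

$$\mathrm{logit}\,p_{ij} = \beta_0 + \beta_1 I(\text{trait1})
 + \beta_2 I(\text{common}) + \beta_3 I(\text{common and rare})
 + \beta_4 I(\text{SKAT}),$$

fitted by generalized estimating equations with genes as clusters, an
exchangeable working correlation (moment estimator, bounded to $[0,0.95]$)
and robust sandwich standard errors — the same gene is tested 12 (or 36)
times, and those counts are correlated. The adjusted variant adds the
causal-signal proportion as a numeric covariate. The "overall
variant-stratum difference" is reported as the joint Wald test of
$(\beta_2,\beta_3)$; the fitter reduces exactly to ordinary binomial
logistic regression when every cluster has one cell, which is one of its
oracle tests (the other compares its sandwich against an independent
clustered-covariance implementation).

## Known limitations

* **Small-sample conservativeness of the variance-component test.** A
  variant with $k$ heterozygous parents contributes a score that is a sum of
  $k$ bounded, symmetric $\pm\tfrac12$ transmissions. For near-singleton
  variants ($k\le 2$) the squared score is almost deterministic, yet the
  $\chi^2$ mixture model assigns it a full chi-square's worth of spread.
  With Beta(1, 25) weights concentrating the statistic on exactly those
  variants, the asymptotic p-values of the $\rho=0$ test are conservative at
  93 trios under a rare-heavy spectrum: its empirical type-I error at
  $\alpha=0.05$ runs near 0.02 (the package's calibration tests report the
  exact value), while the burden test — one aggregated, near-Gaussian
  contrast — is calibrated at the same size. The test suite verifies that
  calibration of the variance-component test is recovered with common
  variants at the same sample size; with rare-heavy spectra it requires
  substantially more informative transmissions per variant (larger cohorts).
  No small-sample moment correction is applied; results at small $N$ with
  ultra-rare variants should be read as conservative.
* Only trio structures are supported; general pedigrees require a different
  conditional law.
* The dilution design fixes the causal set and varies noise variants, so
  "proportion of causal variants" is exact only up to rounding.
* Dichotomous-trait residuals enter the score exactly as $Y-\hat\mu_0$ with
  the transmission-conditional covariance; no additional variance rescaling
  is applied.
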