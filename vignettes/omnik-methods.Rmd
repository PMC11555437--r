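---
title: "OmniK: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OmniK: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OmniK)
```

## The testing problem

A kernel machine regression with a treatment interaction models a
response $y$ for $n$ subjects as

$$ y = \alpha_1 + T\alpha_2 + Z\alpha_3 + f(X)\beta_1 +
   (f(X)\odot T)\beta_2 + \varepsilon, $$

(or the logistic analogue for binary $y$), where $X$ is an $n\times p$
matrix of microbial (or genetic) variants, $T$ a treatment, $Z$
covariates, and $f$ an unknown basis transform. The null hypothesis of
interest is joint: no main effects and no treatment-interaction effects
of the variants, $\beta_1^\top\beta_1 = \beta_2^\top\beta_2 = 0$.

In microbiome studies the variant information usually enters through an
*ecological kernel*: an $n\times n$ positive semi-definite matrix of
between-sample similarities derived from a beta-diversity distance.
The transformed variants $f(X)$ behind such a kernel are unknown and
effectively unrecoverable, which is what rules out methods that need
the variants themselves to form interaction terms.

## Surrogate variants and endogenous kernels

Any PSD kernel is the gram matrix of *some* variant set. Writing
$K = U D^2 U^\top$ and dropping the components with zero eigenvalue
gives $X^* = U D$, an $n \times df$ matrix of orthogonal **surrogate
variants** with $X^* X^{*\top} = K$. Interaction terms can then be
formed from the surrogates instead of the unknown variants:

* $K^M = X^* X^{*\top}$ — main effects (this is $K$ itself),
* $K^I = (X^*\odot T)(X^*\odot T)^\top$, i.e. $K^I_{ij} = T_iT_jK^M_{ij}$,
* $K^B = K^M + K^I$, exactly the gram matrix of $(X^* \mid X^*\odot T)$.

With null-model residuals $r = y - \hat y_0$ from the fit of
$y \sim 1 + T + Z$ (OLS, or ML logistic for binary responses — the
null model is the same whether one starts from the variants or the
surrogates), each target gets a variance-component score statistic
$T = r^\top K^\cdot r$, estimating the summed squared effects without
ever fitting them.

## Permutation calibration and the two-level min-P omnibus

All statistics share **one permutation plan**: $R$ random rearrangements
of the residual vector, applied simultaneously to every endogenous
kernel and every input kernel. The observed arrangement is treated as
one of the rearrangements throughout (the exchangeable convention), so
the set of $R+1$ arrangements is pooled and the p-value of an
arrangement is the fraction of pooled statistics $\ge$ its own (ties
count); the observed statistic's p-value is
$P = (1 + \#\{T^{(r)} \ge T^{(obs)}\})/(R+1)$, with floor $1/(R+1)$.

Because the three endogenous tests are strongly dependent, their
minimum p-value is used as a statistic and recalibrated against its own
permutation null: *every* arrangement — observed and permuted alike —
is converted to its pooled p-value per target, the per-arrangement
minimum over the three targets is taken, and the observed minimum is
compared against all $R+1$ minima. The same construction is applied a
second time across the input kernels, giving per-target omnibus
p-values $P^M_{\mathrm{OmniK}}, P^I_{\mathrm{OmniK}},
P^B_{\mathrm{OmniK}}$, and once more across the three targets for the
overall $P_{\mathrm{OmniK}}$. Keeping the observed arrangement inside
every comparison set is essential: recalibrating minima of
observed-excluded p-values against minima of leave-one-out p-values
(denominators $R$ vs $R-1$) looks innocuous per test, but the support
and self-exclusion mismatch compounds across $3|\Gamma|$ dependent
tests and two nesting levels into a 1-2 percentage-point
anti-conservative bias at the 5% level; the pooled form is exactly
uniform at every level by exchangeability. Everything is computed from
one pass of quadratic forms — $O(R n^2)$ per kernel via matrix
products on the stacked permuted-residual matrix — with no nested
permutation loops; subsetting kernels (`omniKSubset()`) therefore needs
no new permutations.

Rank-based calibration makes every reported p-value invariant to
positive rescaling of the residuals, and exactly uniform (up to
$1/(R+1)$ discreteness) under the null regardless of the response
distribution — the property the test suite checks by simulation.

## Ecological kernels

Seven candidate kernels are the default set $\Gamma$: Jaccard,
Bray-Curtis, unweighted UniFrac, generalized UniFrac at
$\alpha \in \{0.25, 0.5, 0.75\}$, and weighted UniFrac. Distances are
turned into kernels by Gower double-centering of the squared distances,
$K = -\tfrac12 (I - \tfrac{11^\top}{n})\,\Delta^{2}\,(I -
\tfrac{11^\top}{n})$, followed by clipping of negative eigenvalues
(Jaccard and Bray-Curtis are semimetrics and routinely produce a few);
the `psdClipped` flag records when clipping actually removed anything
material (beyond $10^{-8}$ of the top eigenvalue).

Design choices worth knowing:

* counts are converted to per-sample **proportions** before Bray-Curtis
  and all UniFrac weights; no rarefaction. This keeps distances stable
  under sequencing depth; results on data rarefied upstream will differ
  slightly.
* weighted UniFrac is the **normalized** variant (range $[0,1]$), so
  all seven kernels live on a common scale, and generalized UniFrac at
  $\alpha = 1$ coincides with it exactly (asserted to $10^{-10}$).
* presence means count $> 0$, exactly.
* the treatment enters the Hadamard product **uncentred**. With
  $T \in \{0,1\}$ this makes $K^I$ supported on treated pairs; whether
  to centre $T$ first is a genuinely open modelling choice and the
  literal product is implemented. Likewise residuals are permuted
  directly (no covariate-preserving scheme such as Freedman-Lane);
  for observational designs this is a known validity caveat of the
  procedure itself.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nPerm` (R) | 3000 | permutations; p-value resolution is 1/R. The simulation harness uses 1000 |
| `df` | `"full"` | surrogate components kept; 10/20/30 reproduce the reduced-rank reference analyses |
| `alpha` | 0.25/0.5/0.75 | generalized-UniFrac abundance weighting between unweighted- and weighted-like behaviour |
| eigenvalue tolerance | `1e-10` relative | a component counts as "zero" below this; `df` may not exceed the surviving count (error, never silent truncation) |
| clip tolerance | `1e-8` relative | threshold for flagging material negative eigenvalues |

Surrogate column signs are fixed deterministically (largest-magnitude
entry positive). The sign never reaches any result — the endogenous
kernels are invariant — but it makes extraction bitwise reproducible.

## Comparison combiners

`altCombine()` applies Fisher, Brown and Simes to the flat set of
$3|\Gamma|$ per-endogenous-per-kernel permutation p-values, the same
values the min-P omnibus consumes, so the comparison is like-for-like.
Brown's method moment-matches a scaled chi-square using the covariance
of $-2\log p$ estimated from the leave-one-out null p-value matrix —
self-contained, with no distributional assumptions about the
statistics. The package's own p-values are bounded below by $1/(R+1)$;
user-supplied zeros are clamped before taking logs.

Under this positive dependence Fisher's method inflates the family-wise
error badly (its independence assumption is violated in the
anti-conservative direction), while Brown's empirical correction is
roughly calibrated. Simes' test, by contrast, is provably valid under
positive regression dependence, so it is *expected not to inflate*
here; it is included as a comparison combiner, not as evidence of
inflation.

## The simulation harness

`runExperiment()` reproduces a complete operating-characteristic
experiment. Per experiment, one random bifurcating tree and one set of
Dirichlet-multinomial parameters are fixed; per replicate, counts,
covariates, treatment, response and the permutation plan are redrawn.

What the generator emulates:

* **counts**: Dirichlet-multinomial with mean proportions $\pi$ and
  overdispersion $\theta = 1/(1+\sum\gamma)$, total count 10000 per
  sample. Defaults: $p = 100$ taxa, $\pi$ a sorted flat-Dirichlet draw
  (a skewed taxon-frequency profile), $\theta = 0.02$. Parameters can
  also be estimated from a real table (`estimateDMParams()`, Weir-Hill
  moments) to mimic a specific cohort.
* **covariates**: $z_1 \sim \mathrm{Bern}(0.5)$; $z_2$ is correlated
  with the microbiome — 0.5 times the row-mean of the standardized
  abundances of a random 10% taxon subset plus standard normal noise.
  (The generating description "$X'\cdot 0.5$" is ill-typed for a
  matrix; the row-mean is the interpretation adopted.)
* **treatment**: $\mathrm{Bern}(0.5)$ for a randomized trial, or
  $\mathrm{Bern}(\mathrm{expit}(0.5(z_1^s + z_2^s)))$ with standardized
  covariates for an observational design (standardization because the
  raw scale of $z_2$ is arbitrary).
* **effects**: a phylogenetically coherent taxon cluster — one of five
  PAM (k-medoids) clusters on cophenetic distances — carries the
  signal, transformed by $f$ = per-taxon standardization (linear
  relationship) or presence/absence indicator (discrete non-linear
  relationship). Canonical magnitudes: main-only $\beta_1 = 2$;
  interaction-only $\beta_2 = 1$ (gaussian) / $3$ (binomial); both
  $(2, -1)$ gaussian / $(-1.5, 3)$ binomial, with the cluster split in
  half between the two effect types. Fixed coefficients
  $\alpha_1 = 0, \alpha_2 = 1, \alpha_3 = 0.5$.

What it does **not** emulate: real phylogenies (random trees have no
deep clade structure), taxon-taxon ecological interactions, compositional
zero-inflation beyond what the Dirichlet-multinomial induces, library-size
variation (totals are constant), or covariate measurement error. Null
calibration results transfer to real data because the permutation test
is distribution-free under exchangeability of residuals; power results
are indicative only, and per-cluster power is intrinsically
unpredictable (it depends on cluster size, rareness and skewness of the
member taxa), which is why the test suite asserts orderings and
robustness rather than per-cluster curves.

Problem sizes used by the packaged experiments: 1000 null replicates
with $R = 1000$ and $p = 100$ taxa for type-I-error checks (at
$n = 100$ and $n = 200$), and 300 replicates per scenario for power
orderings — sizes chosen so three binomial standard errors at the 5%
level are about two percentage points, tight enough to distinguish
calibration from inflation. The power scenarios use effect cluster 1;
with the canonical effect sizes at $n = 100$ several methods sit near
power 1, so ordering checks carry a small Monte-Carlo slack for ties.

## Numerical and degenerate-input behaviour

* Ties in permutation statistics are resolved by the defining $\ge$ /
  $\le$ counts themselves; no jitter is added. In-theory-tied
  statistics (e.g. permutations that only move residuals among
  untreated subjects, for $K^I$) may differ by float noise; this
  affects individual rank counts by $O(1/R)$ and nothing else.
* A kernel that is numerically zero (no surviving component) is an
  error, as is `df` above the surviving component count.
* A binomial null fit that fails to converge, a degenerate (constant)
  binary response, or quasi-perfect separation is an error, not a
  warning.
* Constant taxa under the standardizing transform are dropped with a
  warning; metadata missing values are a hard error; table/metadata
  sample mismatches are resolved by intersection in count-table order,
  and a table taxon missing from the tree is an error, never a silent
  drop.

## Limitations

Variant-by-variant interactions are out of scope — the surrogate
construction covers variant-by-treatment products only. Asymptotic
(mixture-of-chi-square) p-values are deliberately absent: calibration
is permutation-only, so runtime grows linearly in $R$ and small
p-values are bounded below by $1/R$ (at $R = 3000$, nothing below
$3.3\times10^{-4}$ can be reported). Effect sizes $\beta^*$ are tested,
never estimated or reported.
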