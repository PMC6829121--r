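---
title: "Cross-validating multi-trait genomic prediction: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validating multi-trait genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcv)
```

## The problem

Breeding programs increasingly measure cheap "secondary" traits (spectral
indices, early-life measurements) on the same individuals whose expensive
focal trait they want to predict. Multi-trait GBLUP can exploit those
measurements in two ways: indirectly, through phenotypes of relatives in
the training set (CV1-style prediction), or directly, through the
secondary-trait phenotypes of the individuals being predicted (CV2-style
prediction). The catch is in *evaluation*: when the secondary trait is
measured on the test individuals themselves, their focal phenotype — the
usual cross-validation predictand — shares non-genetic variation with the
secondary phenotype that the CV2 predictor consumed. Naive
cross-validation then over- or under-states CV2 accuracy depending on the
sign of the residual correlation between the traits, and can
systematically pick the worse of two models. `mtcv` simulates this
situation end-to-end and implements four accuracy estimators so their
model-selection behaviour can be compared.

## Model

Two traits on $n$ lines with genomic relationship matrix $K$:

$$Y = U + E,\qquad U \sim MN(0, K, G),\qquad E \sim MN(0, I_n, R),$$

with per-trait phenotypic variances standardized to 1, so

$$G = \begin{bmatrix} h_1^2 & \rho_g h_1 h_2 \\ \cdot & h_2^2 \end{bmatrix},
\qquad
R = \begin{bmatrix} 1-h_1^2 & \rho_R\sqrt{(1-h_1^2)(1-h_2^2)} \\
\cdot & 1-h_2^2\end{bmatrix}.$$

Sampling uses the two-sided Cholesky transform $U = L_K Z_u L_G^\top$,
$E = Z_e L_R^\top$ — exact for the matrix-normal, no eigen-sampling
needed. The standard-normal matrices $Z_u, Z_e$ are drawn once per
replicate and reused across every architecture (common random numbers),
which removes between-architecture Monte-Carlo noise from method
comparisons; `make_draws()` exposes exactly this object.

Partitioning the lines into a training set $o$ and test set $n$
partitions $K$ into blocks $K_{nn}, K_{no}, K_{oo}$. Two derived
matrices drive all predictions: the projection $P = K_{no}K_{oo}^{-1}$
and the Schur complement
$\Sigma_c = K_{nn} - K_{no}K_{oo}^{-1}K_{on}$, the conditional genetic
covariance of test lines given training lines. Both are computed by
solving against $K_{oo}$; the full $K$ is never inverted.

### A note on $(K^{-1})_{nn}$

The CV2 predictor and its variance term are sometimes written with the
symbol $(K^{-1})_{nn}$, which is ambiguous between "the $nn$ block of
$K^{-1}$" and its inverse. We use $\Sigma_c$ (equal to
$[(K^{-1})_{nn}]^{-1}$), because the predictor is then *exactly* the
multivariate-normal conditional mean
$E[u_{n1} \mid u_o, y_{n2}]$ and $V_c = g_{22}\Sigma_c + r_{22}I$ is
exactly $\mathrm{var}(y_{n2}\mid u_o)$. The test suite verifies this
identity against a brute-force dense-joint-covariance oracle to $10^{-6}$
on random instances.

## Predictors

All three predict the focal-trait genetic values of the test lines:

* **single** (univariate GBLUP): $\hat u_{n1} = P\hat u_{o1}$ with BLUPs
  from the univariate REML fit of trait 1 on the training set.
* **cv1** (multi-trait, training phenotypes only): same projection, but
  $\hat u_{o1}$ comes from the bivariate fit, so secondary-trait
  information enters through relatives.
* **cv2** (two-step multi-trait): adds
  $\hat g_{12}\Sigma_c V_c^{-1}(y_{n2} - \hat\mu_2 - P\hat u_{o2})$, the
  regression of $u_{n1}$ on the test lines' own secondary phenotypes
  given the training BLUPs. The two-step structure means no test-line
  data enter model training. It is a plug-in approximation: replacing
  $\hat u_o$ with the true $u_o$ makes it the exact conditional mean,
  which is how the oracle tests validate it.

## REML

Both mixed models are estimated by REML with intercept-only fixed
effects, using the eigendecomposition of $K$ so that each likelihood
evaluation is $O(n)$ after a one-time $O(n^3)$ decomposition
(`grm_eigen()` lets callers share that decomposition across fits on the
same partition, which is what `run_grid()` does).

* Univariate: the likelihood is profiled down to one dimension in
  $h^2 = g/(g+r)$ and maximized by golden-section search
  (`optimize()`, tolerance $10^{-9}$); estimates hugging the $h^2$
  boundary (within $10^{-4}$) are flagged.
* Bivariate: $G$ and $R$ are parameterized through log-Cholesky factors
  (3 parameters each; positive definiteness by construction) and
  maximized by BFGS (relative tolerance $10^{-10}$, 500 iterations).
  Starting values are $0.5\,\mathrm{cov}(Y)$ for both matrices, with a
  diagonal-only restart, then a Nelder-Mead fallback; if everything
  fails the start-value fit is returned flagged `converged = FALSE`
  rather than thrown, so grid runs can record and keep going. Fits whose
  $\hat G$ or $\hat R$ have a condition-number-relative eigenvalue below
  $10^{-6}$ are flagged `singular`. Flagged fits are *kept* in grid
  results (with their flag) because covariance-estimation noise is part
  of the phenomenon under study — hiding it would overstate multi-trait
  performance.

## Accuracy estimators

With true simulated genetic values $u_{n1}$ available, true accuracy is
$\mathrm{cor}(\hat u_{n1}, u_{n1})$. The estimators that must work
without truth:

* **naive**: $\mathrm{cor}(\hat u_{n1}, y_{n1}) / \sqrt{h_1^2}$. Under
  the model $\mathrm{cor}(\hat u, y) = \mathrm{cor}(\hat u, u)\,h$, so
  we divide by $h$; a `h_power` switch exposes division by $h^2$ instead
  for sensitivity analysis. The same factor is applied to every method,
  so the choice cannot affect model *selection*.
* **ebv** (deliberately invalid): correlation with focal BLUPs from a
  bivariate fit of the *complete* data. Provided only to demonstrate its
  upward bias; the test suite asserts the bias.
* **parametric** (selection-index): refit the bivariate model to
  $(\hat u_{n1}, y_{n1})$ on the validation lines only, with $K_{nn}$;
  accuracy $= \hat\rho_g(I,y)\,\hat h_I$. We compute it as
  $\hat g_{Iy}/\sqrt{\hat g_{yy}(\hat g_{II}+\hat r_{II})}$, in which the
  index's own genetic variance cancels — numerically stable when the
  index carries little genetic signal. Run under a 50:50 split so both
  stages have enough lines to estimate covariances.
* **semiparametric**: subtract from the raw correlation the analytic
  bias induced by the residual correlation. Because
  $\mathrm{cov}(e_{n1}, e_{n2}) = r_{12}I$ and only the
  $y_{n2}$-dependent term of the CV2 predictor touches $e_{n2}$, the
  expected excess of $\widehat{\mathrm{cov}}(\hat u^{(3)}_{n1}, y_{n1})$
  over $\widehat{\mathrm{cov}}(\hat u^{(3)}_{n1}, u_{n1})$ is exactly

  $$\hat g_{12}\,\hat r_{12}\,
    \mathrm{tr}\!\left(S\,\Sigma_c V_c^{-1}\right)/(n-1),
    \qquad S = I - \tfrac{1}{n}\mathbf{1}\mathbf{1}^\top,$$

  derived from first principles as the covariance between the
  predictor's $y_{n2}$ term and $e_{n1}$ under sample centering. On the
  covariance scale this identity is exact, and the acceptance suite
  verifies it against a 2000-replicate Monte-Carlo oracle with true
  $G, R$ (3-standard-error agreement). The correlation-scale bias
  divides by the sample standard deviations of $\hat u^{(3)}_{n1}$ and
  $y_{n1}$; the corrected estimate is
  $(\mathrm{cor} - \widehat{\mathrm{bias}})/\sqrt{h_1^2}$. The bias is
  identically zero when $\hat g_{12} = 0$ or $\hat r_{12} = 0$ and its
  sign is $\mathrm{sign}(\hat g_{12}\hat r_{12})$.
* **cv2star**: score predictions against focal phenotypes of
  independently raised genetic copies. *Clone design*: each test line
  contributes two phenotype copies with residual variance $2R$ each
  (each copy is based on half of a line-mean's plots); copy A's
  secondary phenotype feeds the CV2 predictor, copy B's focal phenotype
  is the predictand, and the heritability correction uses the inflated
  phenotypic variance $h_1^2 + 2r_{11}$ — applied to *every* method
  compared, so comparison is unaffected. *Relative design* (80:10:10):
  each test line's surrogate is its most-related held-out line. The
  surrogate assignment processes test lines in descending order of their
  best available relatedness, greedily without replacement, ties broken
  by line order — greedy-by-strongest minimizes forced bad matches when
  relatives are scarce. The suite also documents the failure mode: with
  genetically unrelated surrogates the estimate collapses to zero
  regardless of true accuracy.

## The synthetic population

Real line-breeding GRMs are proprietary, so `simulate_breeding_grm()`
builds one: `n_families` biparental families (four founder haplotypes
each at population allele frequencies $U(0.1, 0.9)$), lines inheriting
one haplotype per parent independently per marker, GRM formed by
VanRaden centering and jittered to an eigenvalue floor of $10^{-8}$.
Within-family pairs are full sibs (expected genomic relatedness 0.5,
inside the 0.3–0.6 calibration band typical of validation-pair
relatedness in line-breeding programs); between-family relatedness is
centered on zero; diagonals are near 1. What it does **not** emulate:
linkage (markers segregate independently), inbreeding (wheat lines are
selfed; their GRM diagonals approach 2), selection-induced allele
frequency gradients, and between-family background relatedness from
shared ancestry. Passing tests on this population therefore demonstrate
properties of the estimators under a clean family structure, not
quantitative transferability of any particular accuracy value to a real
program.

## Study profile and reproducibility

The default desk-scale profile is a 400-line, 40-family, 2000-marker GRM
with 200 replicates per architecture (100 per point for parameter
sweeps), 90:10 training:test splits for the naive and clone designs,
50:50 for the parametric design and 80:10:10 for the relative design.
The full 42-architecture default grid
($h_1^2 = 0.2$, $h_2^2 \in \{0.2, 0.6\}$, $\rho_g \in \{0, 0.3, 0.6\}$,
$\rho_R \in \{-0.6, \dots, 0.6\}$) at this profile runs in well under an
hour on one CPU; a full-scale profile (around 800 lines and 500
replicates, the size of a typical breeding-program study) is a set of
arguments away.

A single root seed feeds `seed_streams()`, which derives independent
named streams for GRM synthesis, trait draws, partition draws and clone
residuals; replicate $r$ offsets each stream deterministically. Results
are bit-identical across runs with the same seed, and varying one
component (say, the partition scheme) leaves the other streams
untouched.

At this scale the headline model-selection failure of naive
cross-validation reproduces qualitatively but not to its full severity:
with 40-line validation sets the per-replicate accuracy estimates are
noisy enough that the naive estimator stumbles onto the better of
{single, CV2} in roughly 15% of opposing-correlation replicates, rather
than under 10% as with twice-larger validation sets — selection noise
shrinks with validation-set size, and `selection_frequency()` reports
binomial standard errors so this can be judged per run.

## Numerical choices and degenerate inputs

* GRM files are dense delimited text with id headers, written at 17
  significant digits so write/read round-trips are bit-identical;
  asymmetry under $10^{-6}$ is averaged away, anything larger is an
  error.
* All solves against $K_{oo}$ and $V_c$ use factorizations
  (`solve`/Cholesky); explicit inverses appear only in test oracles.
* Ties in estimated accuracy count as half a correct selection;
  replicates missing either method's estimate leave the denominator.
* Degenerate phenotypes (identical trait columns, zero variance) yield
  flagged fits or errors as appropriate, never silent nonsense;
  correlations of constant vectors return `NA` with a warning.

## Limitations

Two traits only; intercept-only fixed effects; Gaussian residuals; a
known, dense $K$. The parametric estimator inherits the model's
normality assumptions; the semiparametric correction is derived for
linear-mixed-model predictors with a known kernel and will degrade when
$\hat g_{12}, \hat r_{12}$ are poorly estimated (run the true-parameter
mode in the tests to see the bias-free ceiling). The one-step CV2 fit
(jointly modelling $y_{n2}$ during training) is intentionally out of
scope.
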