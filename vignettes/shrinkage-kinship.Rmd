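---
title: "Methods: shrinkage estimation of the realized relationship matrix and GBLUP"
author: "kinshrink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shrinkage estimation of the realized relationship matrix and GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinshrink)
```

## The model

Genomic prediction treats the breeding values $a$ of $n$ lines as
multivariate normal, $a \sim N(0, \sigma^2 A)$, where $A$ is the additive
(realized) relationship matrix estimated from markers. Given phenotypes
$y = \mu 1 + a + \varepsilon$ with $\varepsilon \sim N(0, \sigma_e^2 I)$,
the mixed model yields BLUE/BLUP solutions — the genomic estimated breeding
values (GEBVs) used to select lines.

This package implements an identity-in-state (IBS) formulation of $A$ in
which the *current* population is its own reference: no pedigree and no
base population is invoked. Writing $X$ for the $n \times m$ dosage matrix
(0/1/2 copies of the counted allele), $p_k$ for the allele frequency of
marker $k$ estimated as half the mean dosage, and $W = X - 2p$ for the
column-centered matrix, the high-density estimator is

$$\hat A = \frac{W W'}{2 \sum_k p_k q_k}, \qquad q_k = 1 - p_k .$$

Two properties follow from the scaling and the centering:

* the mean diagonal element is exactly $1 + f$, where $f$ is the
  population's IBS inbreeding coefficient (1 for fully homozygous panels,
  about 0 under Hardy–Weinberg proportions). Individual diagonal entries
  may exceed 2 — unlike pedigree relationships, these are state quantities
  relative to the current population;
* every row of $\hat A$ sums to zero, so $\hat A$ is positive semidefinite
  with at least one zero eigenvalue. The implied singular normal for $a$
  poses no problem for mixed-model computations (we work in the eigenbasis
  throughout).

### Inbreeding at three levels

`inbreedingSummary()` reports the per-locus gametic correlation $f_k$
(weighted by $\beta_k \propto p_k q_k$), the per-line excess homozygosity
$\phi_i = \sum_k (X_{ik} - 2p_k)^2 / (2\sum_j p_j q_j) - 1$, and the
population coefficient $f$. The three agree exactly:
$f = \sum_k \beta_k f_k = n^{-1}\sum_i \phi_i = \langle A_{ii}\rangle - 1$.
For real-valued (mean-imputed) dosages we evaluate
$f_k = n^{-1}\sum_i (X_{ik}-2p_k)^2/(2 p_k q_k) - 1$, the unique continuous
extension of the gametic correlation that preserves this identity for any
dosages in $[0,2]$; it coincides with the two-gamete definition at integer
dosages. When all $p_k = 1/2$, $\phi_i$ reduces to $2\psi - 1$ with $\psi$
the line's homozygous fraction. Monomorphic markers are retained with
$f_k = 0$ and $\beta_k = 0$ (they contribute nothing to either side of the
estimator), so the marker count $m$ is never silently changed.

## Shrinkage for low marker density

$\hat A$ above is equivalent to plugging the sample covariance
$S = m^{-1} W W' - \langle W_{\cdot k}\rangle\langle W_{\cdot k}\rangle'$
(columns of $W$ treated as $m$ replicate observations of an $n$-vector)
into the decomposition of the relationship matrix. With low-density panels
(a few hundred markers against hundreds of lines), $S$ estimates $n^2/2$
parameters from $nm$ data points and its mean squared error is no longer
optimal. We therefore shrink $S$ toward the diagonal target
$\langle S_{ii}\rangle I$:

$$\hat A^{*} = \frac{\delta \langle S_{ii}\rangle I + (1-\delta) S +
\langle W_{\cdot k}\rangle\langle W_{\cdot k}\rangle'}{2\langle p_j q_j\rangle}.$$

The target preserves the trace, so the inbreeding coefficient is *never
shrunk* — only the off-diagonal structure is damped. At $\delta = 0$ the
estimator equals the plain one exactly (an algebraic identity the test
suite asserts at $10^{-12}$), and $\hat A^{*}$ stays positive semidefinite
for every $\delta \in [0,1]$.

The intensity is chosen analytically to minimize the expected squared
Frobenius error of the covariance estimate:

$$\delta = \frac{m^{-2}\sum_k \lVert Z_{\cdot k} Z_{\cdot k}' - S\rVert^2}
{\lVert S - \langle S_{ii}\rangle I\rVert^2},$$

clamped to $[0,1]$, where $Z$ is $W$ additionally adjusted to zero row
means. The numerator is evaluated through the squared-elements shortcut
$m\sum_{ij}(\Gamma_{ij} - S_{ij}^2)$ with
$\Gamma = m^{-1}[Z^2][Z^2]'$, which the tests verify against the direct
per-column loop at $10^{-10}$. When the denominator is zero, $S$ already
equals the target and $\delta$ is defined as 0. A useful magnitude
heuristic is $\delta \sim n/(m\,\mathrm{CV}^2)$, with CV the coefficient of
variation of the eigenvalues of $S$ (population standard deviation over
mean; the $n$-divisor convention is ours, as the reference convention is
unstated): structured populations have high CV, little estimation
difficulty relative to the target distance, and hence little shrinkage.

Because the row-centered identity
$m^{-1} Z Z' = m^{-1} W W' -
\langle W_{\cdot k}\rangle\langle W_{\cdot k}\rangle'$ holds exactly, the
same $S$ serves both the intensity formula and the estimator.

## REML and prediction

`fitGBLUP()` maximizes the restricted likelihood of
$y \sim N(\mu 1, \sigma^2 A_{tt} + \sigma_e^2 I)$ by profiling the ratio
$\lambda = \sigma_e^2/\sigma^2$ after a single eigendecomposition of the
training block $A_{tt}$. Numerical choices:

* $\log\lambda$ is searched on $[-18.4, 18.4]$ ($\lambda \in
  [10^{-8}, 10^{8}]$): a 64-point grid brackets the maximum, then the zero
  of the analytic score (envelope-theorem derivative of the profiled
  restricted log-likelihood) is located by root-finding to a tolerance of
  $10^{-12}$, falling back to golden-section search when the score is
  numerically flat. The precise localization makes the fit invariant (to
  $10^{-10}$) under adding a constant to all phenotypes;
* eigenvalues of $A_{tt}$ below $10^{-10}$ of the largest are treated as
  exactly zero — directions in which the model carries no genetic
  variance; the phenotypic covariance inverse is never formed;
* a fit whose optimum sits on the search boundary, or whose profiled
  likelihood is flat (e.g. $A \approx cI$, where only
  $\sigma^2 + \sigma_e^2$ is identified), is returned with its `boundary`
  flag set rather than erroring. With noiseless phenotypes the residual
  component correctly collapses to the boundary *when the spectrum of* $A$
  *identifies the ratio*; on near-identity kinship matrices the restricted
  likelihood is nearly flat in $\lambda$ and single-realization estimates
  of the split are unstable — a property of the model, not of the
  optimizer, which the test suite pins against dense grid evaluation of
  the same likelihood.

GEBVs for unphenotyped lines use the cross-covariance rows,
$\hat a_{\mathrm{target}} = \hat\sigma^2 A[\mathrm{target},\mathrm{train}]
\hat V^{-1}(y - \hat\mu 1)$. Two heritability estimators are reported: the
regression plug-in $h^2 = \hat a'(y-\hat\mu 1)/\lVert y-\hat\mu 1\rVert^2$
and the large-population closed form
$h^2 = \sigma^2(1+f)/(\sigma^2(1+f) + \sigma_e^2)$ — the $(1+f)$ factor
reflects that in inbred populations the additive genetic variance exceeds
the relationship-matrix scale parameter by exactly that factor. Only the
large-$n$ form of the expectation is implemented; no finite-$n$ correction
is attempted, so on small panels the two estimators can differ
noticeably.

## What the simulator emulates — and what it does not

`simulatePopulation()` generates dosage panels with two nested levels of
Balding–Nichols drift (Beta-distributed frequencies with mean $p$ and
variance $F\,p(1-p)$):

* **subpopulations** (`divergence`): large first principal component,
  multimodal off-diagonal kinship — the profile of structured diversity
  panels. With two subpopulations and `divergence = 0.5`, the first PC
  captures over 30% of the variance, matching highly structured rice-like
  panels;
* **families within subpopulations** (`familySize = 10`,
  `familyDivergence = 0.4` for inbred panels): this background relatedness
  is essential. Without it, independently sampled lines have true
  covariance proportional to $I$ — the shrinkage target itself — and full
  shrinkage is trivially optimal, a degenerate regime no real panel
  occupies. The defaults reproduce the empirical profile of unstructured
  inbred diversity panels: eigenvalue CV near 1.3 with a first PC of a few
  percent and $f = 1$. For outbred panels, drawing both gametes from the
  family's frequencies converts family divergence into a Wahlund excess
  homozygosity of the same magnitude, so the outbred default is 0.03,
  giving $f \approx 0.03$ as seen in commercial outbred populations.

Markers are resampled (up to 1000 rounds) until the panel-wide minor
allele frequency reaches `mafMin` (default 0.05); an impossible
configuration errors. The generator is fully deterministic given `seed`.

Traits are simulated per the benchmark protocol: breeding values drawn
from the singular normal with covariance equal to the full-marker $A$
(eigenvalues clipped at zero, no renormalization; hence $\sigma^2 = 1$ by
construction), independent $N(0, \sigma_e^2)$ noise added, no fixed effect
($\mu = 0$; the fitted model still estimates it). "Phenotypic accuracy" is
the realized Pearson correlation between phenotype and true breeding value
within a replicate — the benchmark a GEBV must beat to be useful.

The simulator does **not** model linkage disequilibrium, genetic maps,
selection, or multi-generation pedigrees; marker subsets are drawn
uniformly without replacement. Consequently, passing benchmarks here shows
that the estimators behave as the theory predicts under drift-generated
relatedness; it does not certify performance under LD-driven marker
redundancy or strong selection.

## The experiment harnesses

Four harnesses reproduce the benchmark designs at desk scale (sizes are
package defaults chosen to keep a full run in the order of a minute on one
core; all accept a seed):

* `intensityVsDensity()` — mean optimal $\delta$ against marker count. On
  a fixed panel the intensity falls as density grows, and structured
  panels shrink uniformly less than unstructured ones at equal $n, m$;
* `shrinkScan()` — at each $\delta$ on a grid (default 0–0.7 by 0.05, ties
  broken toward smaller $\delta$), the mean squared error
  $n^{-2}\lVert A^{*}_{\mathrm{sub}} - A_{\mathrm{full}}\rVert^2$ against
  the full-marker matrix and the GEBV accuracy from training on simulated
  phenotypes. The analytic intensity tracks the realized MSE argmin;
  the accuracy maximum sits at or slightly above it, so MSE-optimal
  shrinkage is mildly conservative for prediction;
* `accuracyVsHeritability()` — traits with $\sigma_e^2 = 2^u$,
  $u \sim U(-1, 7)$, binned by realized phenotypic accuracy into half-open
  bins centered on multiples of 0.1. The gain from shrinkage grows with
  phenotypic accuracy, while at high heritability the phenotype itself
  overtakes low-density GEBVs;
* `holdoutExperiment()` — a random fraction of lines is masked; shrinkage
  raises GEBV accuracy for the phenotyped (training) lines but leaves
  unphenotyped (test) lines essentially unchanged, the pattern that
  matters for deciding when low-density shrinkage is worth it in a
  breeding program.

Benchmark problem sizes used by the acceptance tests and
`scripts/acceptance.R`: unstructured and structured inbred panels of
$n = 300$ lines by $m = 3000$ markers (subsets of 300–384 markers),
a 250 × 2500 panel with 500 simulations for the heritability sweep, and
40 replicates for the holdout design.

## Known limitations

* Curation order (markers first, then lines, single pass) is a convention;
  panels hovering at the thresholds can differ under the reverse order.
* Mean imputation introduces small amounts of apparent heterozygosity in
  inbred panels, pulling $f$ slightly below 1; downstream formulas accept
  the real-valued dosages exactly.
* The components-based heritability clamps $f$ to $[-1, 1]$; marker-subset
  estimates can overshoot by sampling noise.
* Only a single intercept is supported as a fixed effect; multi-trait
  models, dominance/epistatic matrices and marker-weighted estimators are
  out of scope.
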