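---
title: "Generalized family-wise corrections from order statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized family-wise corrections from order statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfwer)
```

## The problem

A genome-wide association scan tests on the order of $10^6$ markers and asks
whether its most significant result would be surprising under the global
null. If every null p-value were an independent Uniform(0,1) draw, the
answer is classical: the minimum of $n$ uniform p-values has tail
probability $1 - (1-p)^n$, the Dunn–Šidák correction. Real scans violate
the uniformity assumption routinely — residual population stratification,
related individuals, and reliance on asymptotic reference distributions all
shift the null p-value distribution — and then the Dunn–Šidák threshold no
longer controls the family-wise error rate (FWER): a mildly heavy-tailed
null can multiply the false-positive rate several-fold at stringent
thresholds.

`gfwer` keeps the order-statistics machinery but replaces the uniform
assumption with a parametric null fitted to the study's own p-values.

## The model

Work on the transformed scale $u = -\ln p$. Under uniform null p-values,
$U$ is unit exponential. The package's central generalization models $U$ as
gamma with scale $b$ and shape $c$,

$$f(u) = \frac{(u/b)^{c-1} e^{-u/b}}{b\,\Gamma(c)},$$

which contains the unit exponential at $b = c = 1$ and captures both
conservative ($b<1$ or tail-thinning shapes) and anti-conservative
(heavy-tailed) miscalibration with two parameters. For $n$ exchangeable
tests, the $i$-th order statistic ($i$ counted from the bottom; the public
interface takes `rank_from_top` $r$ with $i = n - r + 1$) has the standard
density

$$i\binom{n}{i} F(u)^{\,i-1}\,[1-F(u)]^{\,n-i} f(u),$$

and the top-ranked statistic ($i = n$) has density $n F(u)^{n-1} f(u)$.
The experiment-wise p-value of an observed top hit $x$ is the tail integral
of that density, which integrates in closed form to

$$p_{E,n} = 1 - F(x)^n .$$

With the unit-exponential $F$ this is exactly Dunn–Šidák; with a fitted
gamma it is the generalized correction. Two alternative null families are
provided behind the same interface: a beta model for the p-values
themselves (used by the Monte Carlo calibration study) and a chi-squared
model for studies that record test statistics rather than p-values. For the
chi-squared family the top-rank density is built from the generic
$n F^{n-1} f$ form with chi-squared $F$ and $f$; no separate formula is
transcribed, as the generic form is the definition.

Correlation among tests (linkage disequilibrium) is handled by substituting
an effective number of independent tests $M_\mathrm{eff} \le M$ for $n$;
the formulas are well-defined for real-valued $n$, so fractional estimates
are accepted as-is.

## Estimation

Parameters are estimated from the study's own results, excluding the
markers already past genome-wide significance (default $p <
5\times10^{-8}$, strict) so the fit describes the null component:

* **Matching moments** (default): $\hat b = \sigma^2/\mu$,
  $\hat c = \mu^2/\sigma^2$ from the sample mean and variance of the
  $u$-values. The variance uses the $n-1$ denominator; at study scale the
  difference from $n$ is far below reporting precision, but it is pinned
  down for reproducibility.
* **Maximum likelihood**: profile likelihood in the shape, solving
  $\log c - \psi(c) = \log \bar u - \overline{\log u}$ by bracketed
  root-finding; the left side is strictly decreasing, so the bracket is
  grown geometrically and the root is unique. MLE requires strictly
  positive $u$ (a p-value of exactly 1 contributes $u = 0$ and an infinite
  log-likelihood term).
* **Beta model**: standard method-of-moments; the moments are checked for
  beta-compatibility ($\sigma^2 < \mu(1-\mu)$) before inversion.

Because the null model's fit in the far tail is what the correction
amplifies, a goodness-of-fit check accompanies estimation: a
Kolmogorov–Smirnov supremum distance whose null distribution is obtained by
parametric bootstrap with parameters *re-estimated on every bootstrap
replicate* (999 by default; fewer than 100 is refused). Re-estimation is
essential — with parameters fitted to the data under test, the classical KS
reference distribution is badly conservative.

## Numerical choices

The quantities this package exists to compute live at magnitudes like
$10^{-23}$; the numerical contract is that survival probabilities retain at
least 10 significant digits down to $10^{-40}$.

* Survival functions are always evaluated directly in the upper tail
  (`lower.tail = FALSE`), never as $1 - \mathrm{CDF}$. R's incomplete
  gamma/beta implementations then deliver full double precision at these
  depths; the test suite pins this against frozen values from a 50-digit
  extended-precision oracle.
* $1 - F(x)^n$ is evaluated as `-expm1(n * log1p(-sf(x)))`, which keeps
  relative precision both when the survival probability is tiny and when
  $n\,\mathrm{sf}(x)$ is of order 1. Naive quadrature of the top-rank
  density is hopeless at $p_{E} \approx 10^{-23}$; the adaptive-quadrature
  path is retained (`experimentwise_p_rank(..., method = "quadrature")`)
  as an independent cross-check for moderate tails, where the two routes
  agree to $10^{-8}$ relative.
* Arbitrary-rank tail probabilities use the exact identity
  $P(\text{at least } r \text{ of } n \text{ exceed } x) =
  I_{s}(r, n-r+1)$ with $s = \mathrm{sf}(x)$ (regularized incomplete
  beta), not quadrature, for the same reason.
* FWER thresholds invert the same closed form: the per-test survival level
  is `-expm1(log1p(-alpha)/n)` and the threshold is the model's inverse
  survival function there. This is the exact root of $1 - F(u)^n = \alpha$;
  iterative root-finding would only re-derive it, and a residual check in
  the tests confirms the achieved FWER matches $\alpha$ to $10^{-8}$.
* Rank densities are computed in log space; the $0 \cdot (-\infty)$ corner
  at the support boundary is resolved to its correct limit, and the beta
  model's $u$-scale log-density is written analytically so it stays finite
  where $e^{-u}$ underflows.
* p-values of exactly 0 are rejected, not clamped: a clamped zero would
  silently distort exactly the tail the model is fitted to. `clamp_pvalues()`
  exists for callers who decide to truncate, visibly.
* Ties in ranking are broken by input order (stable sort); exceedance and
  exclusion comparisons are strict (`p < threshold`), so a result exactly
  at a threshold does not count against it.

A classical-literature note: printed forms of the general ranked density
sometimes disagree by one in the exponent of the survival factor depending
on whether the density term is folded in. The package uses
$F^{i-1}(1-F)^{n-i}f$, the standard order-statistic density, which for the
exponential case is identical to the $(n-i+1)$-exponent form with the
density written out.

## The Monte Carlo calibration study

`run_study()` measures realized FWER: each replicate draws $n$ null
p-values from Beta($\nu,\omega$), and the proportion of replicates whose
minimum p-value beats a threshold estimates that threshold's true
family-wise level. The default conditions mirror the calibration
experiment the method was designed around: $n = 10{,}000$ tests,
$5{,}000$ replicates, target level $0.05$, beta shapes spanning
$0.7$–$1.2$. With $\nu = \omega = 1$ both procedures are exact by
construction. With $\nu = 0.9, \omega = 1.1$ the Dunn–Šidák threshold
($5.13\times10^{-6}$ per test) is exceeded by roughly 17% of top-ranked
null results — the analytic value is
$1-(1-F_\mathrm{Beta}(\alpha_{DS}))^n = 0.1726$ — while the gamma-model
threshold (about $1.36\times10^{-6}$) holds the rate near 5%.

`estimation_mode = "per_replicate"` (default) re-fits the gamma model to
each replicate's own $-\ln p$ values, mirroring the actual analyst
workflow of calibrating from the experiment in hand; the reported
`g_alpha` is then the mean of the per-replicate thresholds, and its
spread is parameter-estimation noise (about $\pm$10–15% at
$n = 10^4$). A `"pooled"` mode fixes one threshold from a single
calibration draw for comparison. In simulation no significance-based
exclusion is applied before fitting — every simulated test is null; the
exclusion rule belongs to the real-data workflow.

## What the synthetic generator does and does not emulate

`generate_study()` produces association tables with null p-values that are
uniform, beta, or gamma-on-$u$, plus an optional handful of signals drawn
log-uniform on $[10^{-35}, \text{ceiling}]$ — the magnitude range of top
hits in well-powered scans. Marker ids, chromosomes and positions are
deterministic cosmetic fields (round-robin chromosomes, fixed-stride
positions) and play no role in any computation. The generator emulates the
*distributional* structure the corrections operate on; it does not emulate
linkage-disequilibrium-correlated tests (block-structured correlation
matrices are generated separately for the effective-tests estimators),
genotype-level noise, or realistic genomic spacing. Tests passing on these
fixtures therefore validate the statistical machinery, not robustness to
correlation in the p-value stream itself — for correlated markers the
package's answer is the $M_\mathrm{eff}$ substitution, whose adequacy
depends on the estimator chosen upstream.

## Effective number of tests

Three estimators, all returning a labelled estimate clipped to $[1, M]$:
the eigenvalue-variance formula
$M_\mathrm{eff} = 1 + (M-1)(1 - \mathrm{Var}(\lambda)/M)$; principal
component counting (smallest $k$ capturing 99.5% of the eigenvalue sum by
default); and a least-squares line through published
$(\text{panel size}, M_\mathrm{eff})$ anchors for when genotypes are
unavailable. The matrix interface expects the $r^2$ matrix by convention —
supplying $r$ instead changes the estimate, so workflows should state which
they pass. Fractional $M_\mathrm{eff}$ feeds straight into the corrections.

## Problem sizes in the shipped tests

The test suite chooses sizes that make each statistical claim decidable
without excess: parameter-recovery runs use $10^5$–$10^6$ draws (the scale
at which 1–2% recovery is a meaningful bar), goodness-of-fit calibration
uses 120 repetitions of $n = 1000$ with 149 bootstrap replicates, the
Monte Carlo table is reproduced at its native $5{,}000 \times 10{,}000$
size, and Monte Carlo cross-checks of the rank densities use $2\times10^5$
triplets. Where a published proportion is itself a Monte Carlo estimate,
agreement is asserted within three combined binomial standard errors.

## Known limitations

* The gamma (and beta, chi-squared) families describe *smooth, global*
  departures from uniformity. A null distribution distorted only locally
  (e.g. a spike of p-values near 1 from discrete tests) can fit well in the
  bulk yet misbehave in the tail; the goodness-of-fit test has limited
  power against purely tail-local misfit. Model error propagates directly
  into $p_{E,n}$ — the far tail is exactly what the correction amplifies.
* Fitting on post-exclusion p-values truncates the extreme tail of the fit
  sample. At study scale (hundreds of exclusions among millions of tests)
  the effect on the moments is negligible, but for small studies with many
  signals the fitted null will be biased toward uniformity.
* A Rayleigh–Rice null for test statistics and joint modelling of null and
  alternative components are out of scope, as are false-discovery-rate and
  step-down/step-up procedures.
* $M_\mathrm{eff}$ methods compress the full correlation structure into a
  single number; they inherit the known approximations of that literature.
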