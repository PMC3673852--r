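---
title: "Separate-channel analysis with a common intra-spot correlation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separate-channel analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepchan)
```

## The model and its assumptions

A two-colour experiment hybridizes 2n RNA samples to n arrays. For probe
*g*, array *i*, channel *c* (1 = green, 2 = red), the background-corrected,
normalized log2 intensity is modelled as

$$y_{gic} = x_{ic}^{\top}\beta_g + b_{gi} + \varepsilon_{gic},\qquad
  b_{gi}\sim N(0,\rho\,\sigma^2_g),\quad
  \varepsilon_{gic}\sim N(0,(1-\rho)\,\sigma^2_g),$$

all independent. The design vector $x_{ic}$ encodes which condition was
hybridized to that channel; under the default one-hot parameterization the
coefficients $\beta_g$ are population mean log2 intensities per condition
and every comparison is a contrast. The assumptions that matter:

* **No missing values.** A finite intensity is required for every
  gene/array/channel; missing cells are a hard validation error, not
  imputed. The variance bookkeeping below (fractional df, exact t
  distributions) relies on complete data.
* **Common correlation.** The intra-spot correlation $\rho$ is the
  proportion of total variance contributed by the spot effect. It arises
  from the array technology (shared spot morphology, print-tip, local
  background), not from the biology of any particular gene, which is the
  justification for pooling a single $\rho$ across all genes. The per-gene
  variance $\sigma^2_g$ remains free.
* **Normality on the log scale**, which is what gives the moderated
  t-statistics their exact null distributions.

The spot-wise reparameterization $M = y_2 - y_1$, $A = (y_1+y_2)/2$ turns
two correlated observations into two independent ones with
$\mathrm{var}(M) = 2\sigma^2_g(1-\rho)$ and
$\mathrm{var}(A) = \sigma^2_g(1+\rho)/2$, so
$\tfrac12\log(4\sigma^2_A/\sigma^2_M) = \operatorname{atanh}\rho$. The
whole method is downstream of this identity.

One convention had to be fixed that the theory leaves open: the ordering of
the 2n observations. This package stacks all green channels (arrays 1..n)
then all red channels, so the M/A transformation matrices are the literal
block operations $C_M^\top = (-1,1)\otimes I_n$ and
$C_A^\top = (\tfrac12,\tfrac12)\otimes I_n$. Any consistent ordering is
statistically equivalent; this one keeps the code and the algebra aligned.

## Per-gene two-stratum REML

For each gene the stacked vector $z_g = (M_g, A_g)$ follows a
heteroscedastic linear model on the transformed design $Z$: the first n
observations share $\sigma^2_{Mg}$, the last n share $\sigma^2_{Ag}$. With
exactly two strata the REML score equations can be solved by a direct
fixed point rather than a general scoring algorithm:

1. initialize both variances at the OLS residual mean square;
2. weighted least squares for $\beta$ with weights $1/\sigma^2$ per
   stratum; residuals $e$; leverages $h_i$ = diagonal of the weighted hat
   matrix;
3. update $\sigma^2_s \leftarrow \sum_{i\in s} e_i^2 \big/
   \sum_{i\in s}(1-h_i)$ and repeat.

A fixed point of this iteration satisfies the REML stationarity condition
in each stratum (the update is the score equation rearranged), which the
test suite verifies against a two-dimensional grid maximization of the
explicit restricted likelihood. At convergence the fractional effective
degrees of freedom are $d_M = \sum_{M\text{-rows}}(1-h_i)$ and likewise
$d_A$; they sum to $2n-\mathrm{rank}(Z)$ because leverages sum to the rank.

Numerical guards, all chosen to be strict but fast:

* convergence at maximum relative variance change < `1e-5` (tolerance
  argument), iteration cap 40 — simulated reference-design genes converge
  in about 5 iterations;
* variance floor `1e-10` times the mean squared data scale: a stratum
  collapsing to the floor (e.g. an all-constant gene, or zero M-residuals
  in a saturated block) marks the gene `usable = FALSE`;
* a stratum whose leverage-corrected df falls below 0.01 (saturated by the
  design) likewise flags the gene rather than erroring.

Unusable and non-convergent genes are excluded from correlation pooling —
pooling should only see trustworthy variance ratios — but nothing else
fails: the downstream linear model uses the common $\rho$ and does not
need the per-gene fits.

The leverages that define $(d_M, d_A)$ are those of the gene's own
converged weighted fit. An alternative reading defines them from the
design rescaled by the *common* correlation, but that creates a circular
dependency ($\rho$ needs the d's, the d's need $\rho$); the two agree
exactly when a gene's fitted variance ratio equals the pooled one, and
closely otherwise. The per-gene choice is self-contained and is what the
bias correction below expects (a function of each gene's own df).

## Bias correction and pooling

Each usable gene contributes
$\hat\tau_g = \tfrac12\log(4\hat\sigma^2_{Ag}/\hat\sigma^2_{Mg})$. Since
$\hat\sigma^2_s$ is approximately $\sigma^2_s\chi^2_{d_s}/d_s$ and
$E\log(\chi^2_d/d) = \psi(d/2)-\log(d/2)$, the statistic has bias

$$\mathrm{bias}(d_M,d_A) = \tfrac12\left[\psi(d_A/2)-\log(d_A/2)
  -\psi(d_M/2)+\log(d_M/2)\right],$$

zero for balanced df. This expression follows directly from the chi-square
log-moment identity and is verified in the tests by direct Monte Carlo
(2×10^5 draws at $d_M=3$, $d_A=7$) and by an independent
recurrence-plus-asymptotic-series digamma routine. It is applied per gene,
with each gene's own df, before pooling.

The pooled estimate is a trimmed mean (15% per tail, the conventional
software default for this estimator) of the bias-corrected $\hat\tau_g$,
back-transformed by tanh. The trimmed mean rather than the median keeps
efficiency while making the estimate insensitive to outlier genes; the
non-robust pooled form $\tfrac12\log(4\sum\hat\sigma^2_A/\sum\hat\sigma^2_M)$
is exposed (`pooled_tau`) for diagnostics only, uncorrected, as classically
written. Negative $\hat\rho$ is permitted — the M/A route does not force a
non-negative variance component the way the mixed-model parameterization
does.

Before rescaling, $\hat\rho$ is clamped to $[-0.99, 0.99]$ (with a
warning): both rescale divisors $\sqrt{2(1-\rho)}$ and
$\sqrt{(1+\rho)/2}$ vanish at the boundary, and a pooled estimate beyond
0.99 indicates a degenerate data set rather than a usable correlation.

## Rescaled least squares and contrasts

"Rescaling by" the correlation is implemented as *division* by the
standard-deviation factors — the only reading that makes the model
homoscedastic. After rescaling, every gene is an OLS problem on the common
design, with residual degrees of freedom $2n-\mathrm{rank}(Z)$: both
strata contribute residual information, which is exactly the efficiency
gain over the M-only fit. (A generic "n − p" df formula does not apply
here unless n is read as the number of observations, 2n; the code uses the
explicit count to prevent df bugs.)

The test suite pins the algebraic anchor: OLS on rescaled M/A data equals
generalized least squares on the raw channel data with the block
correlation matrix $\begin{pmatrix}1&\rho\\\rho&1\end{pmatrix}$ per spot,
to 1e−10, across random designs and correlations.

The classic log-ratio fit (`fit_log_ratio`) regresses M-values on the
difference design (red row minus green row). Under one-hot coding that
design is always rank-deficient (only contrasts of conditions are
estimable from ratios), so the fit uses the minimum-norm pseudoinverse
solution and records the design row space; `contrast_fit` then refuses
any contrast outside it. That is the unconnected-design failure mode made
explicit: for islands B/C and D/E, B−C passes and B−D errors, while the
separate-channel fit estimates B−D with variance $4\sigma^2/n$.

For a paired design the A-values carry no information about the treatment
contrast and the two fits give identical point estimates. Their
t-statistics can still differ slightly: the separate-channel residual
variance pools A-stratum residuals into $s_g$, whereas the paired t uses
M-residuals alone. Point-estimate equality is exact; statistic equality is
the balanced-design special case.

## Empirical Bayes moderation

Gene variances get the conjugate scaled inverse-chi-square prior
$(d_0, s_0^2)$, estimated by moment matching on the log scale:
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$ has mean
$\log s_0^2 + \psi(d_0/2) - \log(d_0/2)$ and variance
$\psi'(d/2) + \psi'(d_0/2)$, so $d_0$ comes from inverting the trigamma
(Newton iteration, tolerance 1e−8, ≤ 50 steps — the function is monotone
so the root is unique) and $s_0^2$ from exponentiating the corrected mean.
Excess dispersion $\le 0$ means the variances are exchangeable: $d_0$ is
reported as infinite and $s_0^2 = \exp(\bar e)$, the log-scale limit.
Estimates of $d_0$ above $10^6$ are also reported as infinite — beyond
that the t reference is numerically normal anyway. Infinite $d_0$
propagates cleanly: posterior variances collapse to $s_0^2$ and p-values
use the normal reference.

Posterior variances are the convex combination
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0+d)$ and the moderated
$\tilde t = \hat\beta/(\tilde s\sqrt{v_j})$ is referred to a t
distribution on $d_0 + d$ df. Under a true null this distribution is
exact for any $(d_0, s_0^2)$, which the suite checks by KS uniformity on a
no-DE simulation — the package's central distributional guarantee.

Multiple testing defaults to Benjamini–Hochberg (via `stats::p.adjust`,
cross-checked in tests against a brute-force step-up implementation); a
fixed-λ Storey $\hat\pi_0$ (λ = 0.5) is reported alongside but does not
rescale the q-values — BH is the conservative common denominator, and the
fixed-λ estimator is deliberately simpler than spline-smoothed $\pi_0$
estimators, so its values will differ slightly from theirs.

## Normalization

`normalize_ma` runs within-array loess of M on A (span 0.3, degree 1,
robustifying iterations — the standard settings for MA normalization,
fitted by `limma::loessFit`) followed by between-array quantile
normalization of A. Ties in the quantile step receive the mean of the
reference distribution over their tied positions, a deterministic and
symmetric policy. Operating on M and A rather than on channels keeps the
M-values identical to what a classic log-ratio pipeline would produce —
the combined pipeline changes only A — so method comparisons on the same
data are clean. Loess settings are package choices: the normalization
literature fixes the idea, not the span.

## The simulator

`simulate_two_channel` generates exactly the generative model above:
$\sigma^2_g \sim s_0^2 d_0/\chi^2_{d_0}$, spot effects and residuals as
variance components, baseline mean log2 expression uniform on [6, 14] (a
typical microarray intensity range; a package default), DE genes offset by
±lfc with the sign randomized per gene, all reproducible from a seed.
Defaults $d_0 = 4$, $s_0^2 = 0.25$, lfc = 1 (a 2-fold change, the
conventional benchmark effect size) describe a realistic moderately
variable experiment.

Negative $\rho$ has no variance-component representation
($\sigma^2_b \ge 0$), so for $\rho < 0$ the generator draws each spot's
(M, A) pair directly from its implied bivariate normal and maps back to
channels; the two routes are distributionally identical where both exist.
The estimator admits negative correlations, so the tests need that regime.

What the simulator deliberately does **not** emulate: spatial artifacts,
background noise, intensity-dependent dye bias, or other
normalization-violating trends (normalization tests use purpose-built
fixtures instead), probe-specific dye effects, and within-array duplicate
spots. Passing recovery tests therefore demonstrate correctness of the
estimators under the model, not robustness to preprocessing failures on
real arrays.

## Problem sizes and test design

The recovery and calibration checks run at sizes where the theory's
guarantees are sharp but the suite stays quick: correlation recovery at
G = 5000 genes, n = 8 arrays, $\rho \in \{-0.3, 0.5, 0.85\}$ (tolerance
0.02); prior recovery at G = 10^4 ($d_0$ within 20%, $s_0^2$ within 5%);
null calibration at G = 2000; power ordering over 20 replicates of
G = 1000 at $\rho = 0.65$ with 20% DE genes. GLS equivalence and the REML
grid oracle use 50 and 25 random instances. Oracles are independent
implementations (direct GLS, explicit likelihood grids, brute-force
step-up FDR, series special functions), with limma used as an external
cross-check where the two packages compute the same standard quantity.

## Known limitations

* One correlation for the whole array set: arrays with genuinely
  heterogeneous spot technology (mixed platforms) violate the pooling
  premise.
* Per-gene quality weights, within-array duplicate spots, and
  covariate-dependent variance models are out of scope.
* The log-ratio comparator shares the package's preprocessing; it is the
  right baseline for method comparison, not a reimplementation of any
  specific historical pipeline.
* $\hat\pi_0$ uses a single λ; spline-based estimators will differ
  slightly on the same p-values.
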