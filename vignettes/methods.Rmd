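---
title: "Models and methods behind pestmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pestmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pestmix` implements a joint-exposure ("multipollutant") analysis of
residential proximity to agricultural pesticide use: buffer-based exposure
assessment from use-report records, outcome-supervised Dirichlet-process
clustering of quartile exposure profiles (Bayesian profile regression),
cluster risk characterization against a low-exposure reference, kernel
machine variable-importance ranking, and Moran's I spatial autocorrelation
analysis.  This vignette describes the models, the priors and tunable
parameters, the synthetic-data generator used for validation, and the
numerical choices a maintainer should know about.

## 1. Exposure assessment

Use-report records give, per application: a one-square-mile section
identifier, a date, an active-ingredient name, and kilograms applied.  For
each maternal residence, amounts applied in a section are weighted by the
proportion of the section's land area falling within a 1-km buffer around
the residence:

$$w_s = \frac{\operatorname{area}(\text{section}_s \cap
\operatorname{disk}(x, 1\,\text{km}))}{\operatorname{area}(\text{section}_s)}.$$

The circle-polygon intersection area is computed exactly by Green's
theorem: each polygon edge is split at its circle intersections, and each
sub-segment contributes either a triangle term (inside the disk) or a
circular-sector term (outside).  Coordinates are consumed already projected
to planar meters; projections are the caller's concern, which keeps the
geometry exact and dependency-free.

Per-trimester amounts sum `kg * w_s` over applications dated inside the
intersection of the trimester with a residence-occupancy window.  Date
intervals are closed on both ends; when user-supplied trimesters share a
boundary date, an application on that date counts once, to the earlier
trimester.  A trimester qualifies when at least 75 days of residential
location are known; subjects need at least two qualifying trimesters, and
their pregnancy average is the sum over qualifying trimesters divided by
their number.  Other subjects are excluded and listed in the filter report.

A pesticide is retained when its population median estimate is positive and
there is at least a two-fold difference between the 25th and 75th
percentiles.  The two-fold rule is read inclusively (`q75 >= 2 * q25`), and
a zero `q25` with positive median counts as infinite contrast and is
retained — the reading consistent with published summary tables in which
several retained pesticides have a zero lower quartile.  Percentiles use
the linear-interpolation definition (R type 7) throughout; quartile
boundaries move under other definitions, so the choice is pinned and
documented.  Quartile profiles assign category $k$ by the half-open bins
$(-\infty, q_{25}], (q_{25}, q_{50}], (q_{50}, q_{75}], (q_{75}, \infty)$;
duplicated cut points collapse categories deterministically toward the
lower category.

## 2. Bayesian profile regression

Each subject carries a profile $x_i = (x_{i1}, \dots, x_{iP})$ of quartile
categories.  The model is a Dirichlet-process mixture in its truncated
stick-breaking representation with $C$ components:

* sticks $v_c \sim \mathrm{Beta}(1, \alpha)$,
  $w_c = v_c \prod_{l<c}(1-v_l)$, with $\alpha \sim \Gamma(2, 1)$;
* within component $c$, categories $x_{ip} \sim
  \mathrm{Cat}(\phi_{cp\cdot})$ with
  $\phi_{cp\cdot} \sim \mathrm{Dir}(0.5, \dots, 0.5)$;
* outcome sub-model (when supervision is on):
  $y_i \mid z_i = c \sim N(\theta_c + W_i \beta, \sigma^2)$ with
  $\theta_c \sim N(\bar y, (2\,s_y)^2)$, $\beta \sim N(0, 10^2)$ on
  standardized confounders, and
  $\sigma^2 \sim \mathrm{InvGamma}(2.5, 2.5\,s_y^2)$.

Continuous confounders are centered and scaled by the package itself (and
the centers recorded), so "adjusted expected outcome" always means
confounders at baseline.  All updates are blocked Gibbs; inference code is
in C++ with all randomness drawn from R's RNG, so a single seed controls
every draw.

**Continuous variable selection.**  Each exposure carries a latent weight
$\zeta_p \in (0,1)$ with a Beta(0.5, 0.5) prior; the effective category
probabilities mix the cluster-specific ones with the observed marginal
frequencies, $\phi^*_{cpk} = \zeta_p\,\phi_{cpk} + (1-\zeta_p)\,\rho_{pk}$.
This is implemented by per-cell augmentation indicators
$\gamma_{ip} \sim \mathrm{Bern}(\zeta_p)$ choosing between $\phi$ and
$\rho$, which keeps the $\phi$ update conjugate; $\zeta_p$ itself moves by
random-walk Metropolis on the logit scale against its Beta full
conditional.  The posterior mean of $\zeta_p$ is reported as the exposure's
clustering-support weight; no numerical equivalence with any particular
published "inclusion probability" estimator is claimed, since those
estimators are typically not fully specified.

**Numerical note: log-space sticks.**  Sticks are represented as
$(\log v_c, \log(1-v_c))$ and sampled through log-space gamma draws.  With
double-precision `rbeta`, a stick with a tiny second shape parameter rounds
to exactly 1, which pins the concentration parameter near zero — an
absorbing floating-point trap that the log-space representation removes.
This matters: the successive-conditional validator (below) fails
dramatically without it.

**Truncation.**  The default truncation is 50 components.  Adequacy is
judged by the 99th percentile of the per-draw top occupied component index
staying below `truncation - 5`; the absolute maximum is not used because a
Gamma-prior concentration routinely spawns transient singletons at high
stick indices even when the truncated tail mass is negligible
(~$(\alpha/(1+\alpha))^{C}$).

**Outputs.**  The co-clustering (similarity) matrix $S_{ij}$ is the
fraction of retained draws allocating $i$ and $j$ together.  The "best"
partition is, by default, the sampled partition minimizing
$\sum_{i<j}(\mathbb{1}[z_i = z_j] - S_{ij})^2$; a
partitioning-around-medoids alternative on $1-S$ is provided because the
literature uses both and does not always say which.  The reference cluster
maximizes the mean share of members in the lowest quartile across all
pesticides (ties to the smallest id).  Cluster-level adjusted-outcome
posteriors average $\theta_{z_i^{(t)}}^{(t)}$ over the best cluster's
members at each sweep, yielding per-cluster posterior means, 95% credible
intervals, differences versus the reference, and deficit probabilities.

**Sampler validation.**  `bpr_getting_it_right()` runs Geweke-style
successive-conditional validation: parameters from the prior with data
re-simulated each cycle through the transition kernels must reproduce the
prior moments of $\alpha$, $\sigma$, and each $\zeta_p$.  The comparison
uses batch-means Monte Carlo standard errors on the dependent chain.  This
jointly exercises every conditional update, including the augmentation
scheme, and is part of the test suite.

## 3. Cluster characterization

Heat-map labels place the within-cluster median of each continuous
estimate into the population quartile bins ("very low" ... "very high"),
with a cumulative column computed identically on row sums.  Even-sized
clusters use the lower median so the label is always an observed value's
bin.  Labels are computed from continuous values against population cut
points, not from the categorical profiles, so they are invariant to
tie-collapsing during discretization.  Clusters are ranked by within-
cluster median cumulative use (median and IQR reported; ties by id).  When
the outcome is excluded from clustering, `second_stage_regression()` fits
ordinary least squares of the outcome on cluster indicators plus
confounders with normal-theory intervals.

## 4. Kernel machine model with hierarchical selection

The outcome model is $Y = h(z) + W\beta + \varepsilon$ with $h$ never
sampled pointwise: it is marginalized into
$Y \sim N(W\beta, \sigma^2 (I + \lambda K))$,
$K_{ij} = \exp(-\sum_p r_p (z_{ip} - z_{jp})^2)$ over the currently
selected exposures.  With nothing selected, $K$ is the all-ones matrix (the
$r \to 0$ limit, an absorbable random intercept) — so selection moves cost
almost nothing when $\lambda$ is small, which is what keeps null-data PIPs
near their prior.  Each group (chemical class) has a Bernoulli activity
indicator with prior probability 0.5, and an active group contributes
exactly one member — the strictest reading of hierarchical selection in
which grouped exposures never enter the same model, chosen to mirror its
collinearity-handling purpose.  Smoothness parameters have a Uniform(0,
100) prior; activation proposes the new member uniformly and its $r$ from
the prior (so proposal densities cancel), and within-model moves are
log-scale random walks.  $\beta$ and $\sigma^2$ are conjugate on the
marginalized likelihood; $\lambda \sim \Gamma(1,1)$ moves by log-scale
random walk.  Exposures are standardized internally.  Group PIPs are
active-draw fractions; conditional PIPs are member shares among a group's
active draws (summing to one within a group; `NA` for never-active
groups).  The marginalized likelihood is tracked through the exponent
matrix $E=\sum_p r_p D_p$ rather than incremental kernel multiplication,
which would overflow when removing a large-$r$ member.

## 5. Spatial statistics

Global Moran's I uses $I = (n/S_0)\, z^\top W z / z^\top z$ on centered
values, with $E[I] = -1/(n-1)$ and a two-sided permutation p-value
$p = (1 + \#\{|I^*| \ge |I|\})/(B+1)$.  Local Moran's I is
$I_i = (z_i/m_2) \sum_j w_{ij} z_j$ with conditional permutations (hold
$i$, permute the rest), no multiplicity adjustment by default and an
optional Benjamini-Hochberg flag.  The default weights are row-standardized
8-nearest neighbors: residences are irregular points, k-nearest guarantees
no islands, and the source analyses do not state their scheme — so the
scheme is explicit configuration recorded in output metadata, and no
numeric reproduction of any published Moran statistic is claimed.  Kernel
density surfaces use a Gaussian kernel (`MASS::kde2d`, whose bandwidth
argument is four times the kernel sd — the wrapper converts) on a grid
padded by four bandwidths so the raster integrates to one within 2%.

## 6. The synthetic-data generator

No cohort data are deposited, so every downstream stage is exercised on
synthetic scenarios with known ground truth.

* **Application amounts** are zero-inflated log-normal.  A latent Gaussian
  per (section, pesticide) drives both occurrence (thresholded at the
  zero-inflation quantile) and log-amount, so occurrence and magnitude are
  positively coupled, and marginals are right-skewed with medians well
  below means — the shape use-report summaries consistently show, with
  some pesticides' medians one to two orders of magnitude below their
  means.
* **Within-class correlation** comes from a one-factor Gaussian copula: a
  shared per-(section, class) factor with loading
  $\sqrt{\rho}$ ($\rho = 0.8$ by default), the simplest mechanism that
  reproduces a blocked correlation structure with organophosphate pairwise
  Spearman correlations in the 0.7-0.9 range.  The latent fields are
  persistent at section level with a small (20%) per-period innovation;
  fully period-level noise would average out of pregnancy-long aggregates
  and push the realized correlations of the aggregates toward 1.
* **Spatial contiguity**: cluster multipliers attach to contiguous column
  blocks of the grid and residences are placed inside their cluster's
  block, so cumulative use is positively spatially autocorrelated and the
  spatial stage has planted signal.
* **Outcome**: true cluster effect + linear confounder term + Gaussian
  noise, with ten default confounders mirroring the usual covariate set
  (home environment, poverty, child age, sex, language, maternal
  education and verbal ability, country of birth, depression, log10
  urinary DAP metabolites).
* **Residual sd**: the realistic scenario default is 9 (the adjusted-FSIQ
  residual scale implied by published credible-interval widths).  The
  named recovery preset `preset_fsiq_recovery()` (three clusters, planted
  effects $0, -6.9, -6.4$ on the FSIQ scale, $n = 300$) instead uses
  residual sd 4.5, chosen by design analysis so a cluster-vs-reference
  mean difference has Monte Carlo SE $\approx 0.64$ and the planted
  effects are statistically identifiable at that sample size; at sd 9 the
  realized sample differences themselves fluctuate by more than the
  recovery band, and no estimator could pass.

What passing recovery tests shows — and what it does not: the generator
plants discrete, well-separated joint-use patterns with exchangeable
subjects; real exposure data have continuous gradients between patterns,
spatially structured confounding, and measurement error from the proximity
proxy itself.  Recovery results certify the estimation machinery, not the
epidemiology.

## 7. Pipeline and reproducibility

`run_pipeline()` sequences simulate, build-exposure, fit-bpr (with and,
for the sensitivity comparison, without outcome feedback), characterize,
fit-bkmr, and spatial stages from one YAML-configurable object, writing
every artifact plus a manifest with the config echo (no silent defaults),
per-stage seeds derived deterministically from one master seed, and MD5
checksums of all artifacts.  Reruns with the same master seed are
byte-identical.  The shipped configuration uses a 120-subject scenario
with 20,000 sweeps after 2,000 burn-in for the profile-regression stages
and 3,000 kernel-model iterations — sizes chosen so a complete run with
the sensitivity comparison takes a few minutes on one CPU; production
analyses should raise the sweep counts (the model defaults are 200,000
sweeps after 20,000 burn-in) and check the confounder-effect trace plots
(`plot_bpr_traces()`).

## 8. Known limitations

* Volatility, degradation, deposition, and application-method weighting
  are not modeled in exposure assessment; estimates are proximity proxies.
* The profile-regression truncation (50) targets cohort-scale n; very
  large n or very diffuse concentration priors need a larger truncation.
* The kernel model's exactly-one-member-per-group encoding is one reading
  of hierarchical selection; exposures that genuinely act jointly within a
  class are not representable in a single draw.
* Binary/discrete variable-selection variants, survival or binary outcome
  sub-models, and prediction for new profiles are out of scope.
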