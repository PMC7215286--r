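---
title: "Bayesian disadvantage-index mapping of areal outlet rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian disadvantage-index mapping of areal outlet rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndimap)
```

## The problem and the model

Counts of retail outlets (tobacco retailers, vape shops, or any point
amenity) vary strongly across census tracts, and part of that variation
tracks neighborhood socioeconomic disadvantage.  Two features make naive
regression unsatisfactory: the socioeconomic covariates are mutually
correlated, so single-variable coefficients are unstable; and outlet rates
are spatially autocorrelated, so independent-error models misstate
uncertainty.  `ndimap` addresses both with a hierarchical Poisson
relative-risk model whose covariate effect enters through a single estimated
index.

For tract $i$ with outlet count $y_i$ and $h_i$ households,

$$y_i \sim \text{Poisson}(\theta_i E_i), \qquad
  E_i = r\,h_i, \qquad r = \frac{\sum_i y_i}{\sum_i h_i},$$

so $\theta_i$ is the tract's risk relative to the overall outlets-per-household
rate, and $\sum_i E_i = \sum_i y_i$ by construction.  The log relative risk
takes one of four nested forms of increasing flexibility:

$$\log \theta_i = \beta_0 + \beta_1 \sum_{j=1}^{C} w_j q_{ij} +
  \begin{cases}
    u_i & \text{(1: unstructured)}\\
    v_i & \text{(2: ICAR spatial)}\\
    u_i + v_i & \text{(3: convolution)}\\
    a_i u_i + (1 - a_i) v_i & \text{(4: convolution mixture)}
  \end{cases}$$

Here $q_{ij} \in \{0,\dots,9\}$ is the decile score of covariate $j$ in
tract $i$ after orienting every variable so that larger means more
disadvantaged, and the weights $w$ live on the simplex with a Dirichlet
prior — the weighted-quantile-sum construction.  The index
$\sum_j w_j q_{ij}$ ranges over $[0, 9]$, $w_j$ reads as the relative
importance of variable $j$, and a weight above $1/C$ (0.083 for the default
$C = 12$) marks a variable contributing more than an equal share.

The unstructured effects are exchangeable, $u_i \sim N(0, \sigma_u^2)$.  The
spatial effects carry an intrinsic conditional autoregressive (ICAR) prior
built on binary queen contiguity: $v_i \mid v_{-i} \sim
N(\bar v_{\omega_i},\, 1/(\tau_v \delta_i))$ with $\bar v_{\omega_i}$ the
mean over the $\delta_i$ neighbors and $\tau_v = 1/\sigma_v^2$.  The mixture
weights $a_i$ have a Beta(1,1) prior, the intercept is flat, the index
coefficient has a Normal prior whose scale $\sigma_1$ — like $\sigma_u$ and
$\sigma_v$ — is Uniform(0, 100).

## Parameters that matter, defaults, and why

* **Decile coding 0–9** (not 1–10).  A tract at the bottom decile of every
  variable then has index 0 regardless of the weights, which makes
  $\beta_0$ the log relative risk of the least-disadvantaged profile.  The
  coding is a convention, exposed through `decile_scores()`; ties share the
  score of their lowest rank block, which makes scores invariant under
  monotone transforms of the covariate.
* **Dirichlet parameters** default to all ones (flat on the simplex):
  the weakest symmetric assumption.  `ndi_prior(alpha =)` takes any
  positive vector.
* **Index-coefficient prior mean** defaults to 0.  A prior centred at 1 on
  a log-relative-risk coefficient — per index *decile* unit — would be a
  strong and unusual commitment (it corresponds to RR $e^1 \approx 2.7$ per
  unit); published specifications of this model family have printed
  Normal(1, $\tau_1$), which we read as a likely typo for a vague
  zero-centred prior.  Both are available: `ndi_prior(beta1_mean = 1)`
  reproduces the printed specification.
* **Scale prior bound** 100 on $\sigma_u, \sigma_v, \sigma_1$, the standard
  wide uniform used in disease mapping.
* **Mixing** is per-tract, matching the subscripted mixture specification;
  `ndi_control(global_mixing = TRUE)` shares a single mixing value, a
  simpler alternative worth comparing by DIC.
* **Exceedance settings**: risk threshold $c = 1$ and cutoff 0.90 on
  $q_{ic} = \frac{1}{G}\sum_g I(\theta_i^{(g)} > c)$; tracts above the
  cutoff are reported as significantly elevated.  Both are arguments with
  these defaults.
* **MCMC protocol**: `ndi_control()` defaults to a fast desk profile
  (6,000 iterations, half burn-in); `paper_protocol()` switches to the long
  single-chain protocol (60,000 iterations, 30,000 burn-in, thinning 1).

## The sampler and its numerical choices

Correctness is defined by the stationary distribution, so the update
mechanics are chosen for reliability in plain R:

* adaptive random-walk Metropolis within Gibbs, acceptance targeted at
  0.44 per block, with Robbins–Monro adaptation **frozen at the end of
  burn-in** so retained draws come from a fixed kernel;
* weights move by random-pair mass-exchange on the simplex (a logit-scale
  walk on the two-component split), which mixes far better than a
  fixed-reference additive-logistic walk when some weights are near zero;
* $u_i$, $a_i$ and, per graph-coloring class, $v_i$ are updated as
  vectorised single-site moves (no two adjacent tracts in a class, so the
  parallel accept/reject is exact);
* each scale parameter additionally gets a joint scaling move that rescales
  the scale and its latent field together ($\sigma' = \sigma e^\varepsilon$,
  field multiplied by $e^\varepsilon$); the prior terms and transform
  Jacobian collapse to $e^\varepsilon$ times the likelihood ratio.  Without
  it, single-coordinate walks traverse the (scale, field) ridge slowly and
  scale posteriors mix poorly;
* the ICAR field is recentred to sum to zero within each connected
  component after every sweep, the removed level being absorbed into the
  flat intercept.  On a connected graph this joint move is exactly
  measure-preserving for the pure ICAR and convolution variants; for the
  mixture variant (and for multi-component graphs) it is the conventional
  disease-mapping approximation, since the shift is only absorbed exactly
  where the mixing is uniform.  Island tracts (no neighbors) carry no
  spatial information and have $v_i$ pinned at 0;
* initialisation is neutral: $\beta_0 = \beta_1 = 0$ (note
  $\log(\sum y / \sum E) = 0$ by construction), $w = \alpha/\sum\alpha$,
  $u = v = 0$, $a = 0.5$, all scales 1;
* the incremental linear-predictor bookkeeping is refreshed from scratch
  every 512 iterations to keep floating-point drift out of long chains.

Degenerate inputs are rejected early: zero-household tracts are excluded
with a report before fitting (they carry no rate information), all-zero
counts refuse to fit, and out-of-support proposals (scales outside
$(0, 100)$, boundary weights) are rejected by the prior.

Diagnostics follow standard practice.  The Geweke z compares the first 10%
against the last 50% of a trace with spectral variance estimated by a
Bartlett lag window of width $\lfloor\sqrt{n}\rfloor$ — the diagnostic's
inventor left the estimator free, so the constants are fixed and documented
here; $|z| < 2$ is the convergence call.  DIC uses
$p_D = \bar D - D(\hat\psi)$ where $D(\hat\psi)$ plugs the posterior means
of every linear-predictor component ($\beta_0$, $\beta_1$, $w$, $u$, $v$,
$a$) into the deviance; $p_D$ is sensitive to this plug-in choice, which is
why it is pinned down here.  Deviance includes the $\log y_i!$ constant;
it cancels in DIC differences.  A DIC drop of 10 or more between variants
is flagged as a meaningful improvement.  Moran's I (binary weights by
default, matching the model's contiguity; row-standardised by option) with
a permutation pseudo p-value screens the crude rates for spatial
autocorrelation before one reaches for variants 2–4.

## What the synthetic generator emulates — and what it does not

`sim_config()` / `simulate_tracts()` generate the structure the model
assumes: a queen-contiguous lattice, covariates drawn from a Gaussian
copula with exchangeable rank correlation (default $\rho = 0.5$, a typical
magnitude for tract-level socioeconomic indicators) mapped through
Beta-like proportion and lognormal-like amount marginals, lognormal
households (median about 1,500, matching the order of magnitude of real
tracts), and counts $y_i \sim \text{Poisson}(\theta_i^* E_i)$ from a chosen
true variant.  The overall rate is scaled so the mean expected count per
tract is about 3 — the regime of a common outlet type; `ey_target = 0.1`
exercises the zero-heavy regime of rare outlet types.  A configurable
fraction of tracts receives one missing covariate cell to exercise the
exclusion filter.

The generator deliberately does **not** emulate: survey sampling error in
the covariates (the real motivation for decile coding), irregular tract
geometry (tests that pass on lattices say nothing about sliver polygons or
topology errors), outlet placement along road networks, or
spatially-varying household density correlated with disadvantage.  Passing
recovery tests on this generator therefore demonstrates the correctness of
the machinery, not the field validity of any substantive estimate.

A note on the limits of weight recovery: with 400 tracts, mean expected
count 3 and correlated covariates, the posterior SD of an individual index
weight is roughly 0.03–0.05 — larger than the spacing between weights in
any dense 12-variable truth.  Dominant weights are identified reliably;
the full ranking of small weights is recovered only in a rank-correlation
sense and noisily so.  At sample sizes in the thousands of tracts the
picture sharpens considerably.

## Problem sizes used by the tests

The shipped checks run, among others: a 6-tract instance whose exact
(quadrature) posterior the sampler must match within 2%; prior-only runs
on an 8-tract grid (50,000 iterations) reproducing Dirichlet, Beta and
Uniform moments; 20×20-lattice recovery runs at 12,000 iterations; and a
15×15 DIC comparison at 10,000 iterations.  These sizes were chosen so the
whole suite completes in minutes on a single core while leaving each check
comfortably outside its Monte-Carlo error.

## Known limitations

* Queen contiguity is detected through shared snapped vertices — exact for
  lattices and for tract layers with common boundary nodes, but a vertex
  lying strictly inside another polygon's edge is not seen.  Supply a
  curated GAL file for production geographies.
* Point-in-polygon treats coordinates as planar; at continental scales or
  near the antimeridian a proper geodesic library should assign outlets.
* The ICAR recentring is approximate for the mixture variant, as discussed
  above.
* Single chain by design (matching the protocol this model family is run
  with); pass different seeds to `ndi_fit()` for an ad-hoc multi-chain
  check.
* No multiplicity adjustment of exceedance calls — hotspot flags at cutoff
  0.90 are descriptive, not familywise-error-controlled.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(rows = 10, cols = 10, C = 6, beta1_true = 0.2,
                  variant = 3, sigma_v_true = 0.5, seed = 1)
sim <- simulate_tracts(cfg)
dat <- filter_missing(sim$data)
fit <- ndi_fit(dat, graph = sim$graph, variant = 3, seed = 2)
summary(fit)
exceedance_probabilities(fit)          # hotspot table
compare_dic(ndi_fit(dat, graph = sim$graph, variant = 1, seed = 2), fit)
```
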