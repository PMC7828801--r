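---
title: "Methods: spatio-temporal Bayesian disease mapping with arealrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal Bayesian disease mapping with arealrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`arealrisk` implements a complete small-area analysis of mortality and
environmental exposure on an areal lattice: indirect standardisation and
SMR estimation, spatial autocorrelation testing, descriptive conjugate
models, a grid of eight hierarchical Poisson log-linear disease-mapping
models with informative-prior propagation, exceedance-probability risk
classification, and predictive model comparison. This vignette explains
the statistical machinery, the choices we made where the design was open,
and what the synthetic-data generator does and does not emulate.

## The standardisation layer

Indirect age–gender standardisation removes compositional differences
between areas before any risk is estimated. With strata $j = 1,\dots,40$
(2 genders × 20 age classes), stratum risks are estimated from the whole
lattice,

$$\mathrm{Risk}_j = \frac{\sum_i \mathrm{Count}_{ij}}{\sum_i \mathrm{Population}_{ij}},
\qquad e_i = \sum_{j=1}^{40} \mathrm{Population}_{ij} \cdot \mathrm{Risk}_j ,$$

and the standardised mortality ratio is the Poisson MLE
$\widehat{\mathrm{SMR}}_i = y_i / e_i$ under $y_i \sim
\mathrm{Poisson}(e_i \theta_i)$. Because the risks are internal, expected
and observed totals are conserved within each standardisation stratum set
($\sum_i e_i = \sum_i y_i$, asserted to $10^{-9}$ in the tests). 95%
limits use the exact Poisson (Garwood) construction from chi-square
quantiles, with the lower bound defined as 0 when $y = 0$.

Two conventions were open and are fixed as follows. Risks are
re-estimated **per year** against the fixed reference-year population
(`year_mode = "per-year"`), which keeps the conservation identity exact
within every year; a pooled mode is available. Rounding (e.g. crude rates
per 1000 at two decimals) is display-only; all downstream computation
uses full precision.

Indirect standardisation needs stratum-level death counts. The on-disk
bundle therefore carries `deaths_strata.csv` alongside the area-level
`deaths.csv`; the generator simulates deaths at stratum level so that the
two are consistent by construction.

## Descriptive Bayesian models

The gender balance of deaths is modelled per year with the conjugate
beta-binomial $y \sim \mathrm{Binomial}(\pi, n)$, $\pi \sim
\mathrm{Beta}(1, 3)$, updated in closed form. A "trend" between years is
declared absent when every pairwise posterior probability
$P(\pi_t > \pi_u)$, estimated by Monte-Carlo draws from the two
independent posteriors, lies strictly inside $(0.05, 0.95)$. This
operationalises a qualitative "no clear trend at PP > 0.05" criterion as
a symmetric pairwise-interval rule; the whole pairwise table is returned
so users can apply their own cut.

Subarea differences in SMR are assessed with a robust hierarchical
pooling model on the subarea-year mean SMRs (unweighted means of area
SMRs — the weighting was unspecified, and the unweighted mean treats
small rural areas and towns symmetrically):

$$\mathrm{SMR}_\delta \sim t_{10}(\theta_s, \sigma), \qquad
\theta_s \sim \mathrm{N}(1, 10^2), \qquad
\sigma^2 \sim \text{Scaled-Inv-}\chi^2(10, s^2),$$

with the prior scale $s^2$ running over a grid of 100 values in
$[0.1, 1.5]$. How results across the grid should be combined was
unspecified; we report the full grid and judge subareas "not
significantly different" when their 95% posterior intervals overlap at
**every** grid point (the most conservative reading). Sampling uses a
Gibbs sampler on the normal scale-mixture representation of the
Student-t ($x_k \mid \lambda_k \sim \mathrm{N}(\theta, \sigma^2 /
\lambda_k)$, $\lambda_k \sim \mathrm{Gamma}(\nu/2, \nu/2)$), for which
all conditionals are conjugate. The $\theta_s$ prior is centred at the
null SMR of 1 with SD 10 — weak on the SMR scale.

## Spatial autocorrelation

Moran's I uses binary ("dichotomous") first-order contiguity weights by
default, matching the adjacency definition of the modelling layer
(row-standardised weights behind a flag):

$$I = \frac{n}{S_0} \cdot \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},
\qquad z = x - \bar x .$$

Significance is Monte-Carlo: `n_sims` random permutations of the values
over the areas, with the plus-one estimator $p = (1 + \#\{I^* \ge
I\})/(n_\mathrm{sims}+1)$ so $p$ is never 0. The default alternative is
one-sided for positive autocorrelation (the scientifically relevant
direction for a pollution field); a two-sided option exists.

## The eight-model grid

The modelling layer crosses a fixed component (A: intercept + covariates;
B: additionally a linear year trend) with a random component (M1 none,
M2 exchangeable/IID, M3 intrinsic CAR, M4 the Besag–York–Mollié
convolution of both), all as Poisson log-linear models with the log
expected count as offset:

$$\log \mu_{it} = \beta_0 + \beta_{pm}\,\mathrm{pm}_{it}
+ \beta_{r}\,\mathrm{rural}_i + [\beta_{y}\,(t - t_0)]
+ u_i + v_i + \log e_{it}.$$

Covariate coding: PM2.5 is centred at its grand mean over all area-years
(global, not per-year centring — the per-year alternative would absorb
the annual means the trend term is meant to capture) and scaled by
15 µg/m³, so $\exp(\beta_{pm})$ is the rate ratio per 15 µg/m³
increment; `rural` merges urban and peri-urban into the reference;
the year is scaled with respect to the first study year. Exponentiated
coefficients from a Poisson model are rate ratios; we label them RR
throughout (they are sometimes reported as ORs in this literature).

Phase-1 priors are $\mathrm{N}(0, 3^2)$ on every coefficient — "SD 3 on
the log scale", implying a 95% prior interval of about $\pm 5.88$, wide
enough to be non-informative for any plausible epidemiological effect —
and Inverse-Gamma(0.01, 0.01) on random-effect variances (a half-normal(0,1)
alternative on the SD is available behind `hyper_family`, since
IG($\varepsilon,\varepsilon$) is known to behave badly when the variance
is near zero).

**Random effects.** IID intercepts $u_i \sim \mathrm{N}(0, \sigma_u^2)$
are shared across years within an area, so RR estimates are temporally
smoothed by the area intercepts and the contiguity matrix is one constant
matrix rather than one per year. The ICAR prior is the intrinsic pairwise
difference prior on the contiguity graph. We sample it **exactly in the
spectral basis of the graph Laplacian** $Q = D - W$: writing $Q = V
\Lambda V^\top$ and dropping the null (constant) eigenvector, $v = V u$
with $u_k \sim \mathrm{N}(0, (\tau \lambda_k)^{-1})$ is the ICAR field
with the sum-to-zero constraint holding *exactly* by orthogonality. This
replaces the usual soft constraint (a tight normal prior on the mean of
the effects): it is equally standard, removes a tuning constant, and
makes the improper prior proper on the constrained subspace, which is
what a generic MCMC engine needs. BYM is the classic two-variance
convolution $u + v$ (not the rescaled BYM2), matching the cited model
form. ICAR/BYM require a connected graph and refuse a disconnected one.

**Sampling.** Models are fitted with JAGS through `rjags`, with the
`glm` module loaded for block sampling of the log-linear likelihood.
Chains are independently seeded from one seed; the first half of each
chain is warmup by default. Per-observation Poisson log-likelihoods are
retained as model nodes for WAIC/LOO. Convergence is gated on the
Gelman–Rubin $\widehat R \le 1.01$ of all reported parameters
(coefficients and variances); a fit exceeding the gate is returned
*flagged with a warning*, never silently. At full scale the reference
configuration is 4 chains × 10,000 iterations (20,000 retained draws);
exceedance probabilities are computed as relative frequencies over all
retained draws — the estimand is identical to resampling a nominal
100,000 draws, without the extra resampling noise.

**Prior propagation.** Later phases condition on earlier ones to curb
the collinearity between a spatially autocorrelated exposure and the CAR
random effect: each coefficient prior becomes Normal(posterior mean,
posterior SD) of the previous phase, and each variance hyperprior is
re-centred as Inverse-Gamma(shape 2, rate = previous posterior median),
whose mean equals that median. The exact hyperprior mapping between
phases was open; this one is simple, proper, and reduces the posterior
SD of $\beta_{pm}$ in the collinear regime (asserted by simulation in
the tests). In the pipeline, M2 conditions on M1, M3 on M2, and M4 takes
its IID variance prior from M2, its ICAR variance prior from M3, and its
coefficient priors from the most recent fit. Propagation refuses an
unconverged source fit.

**Risk classification.** Per area-year, the posterior median of
$RR = \exp(\eta)$ (linear predictor without the offset) and the
exceedance probability $PP = P(RR > 1)$ are reported; areas are "high
risk" when $PP > 0.90$ and "low risk" when $P(RR < 1) > 0.90$. For any
continuous posterior the latter is identical to $PP < 0.10$; the
two-sided phrasing only matters for the degenerate case of a posterior
with mass exactly at 1, which is then (correctly) neutral.

## Model comparison

WAIC and PSIS-LOO are computed from the per-observation log-likelihood
draws on the deviance scale (lower is better): $\mathrm{lppd}_i = \log
\frac1S \sum_d e^{\ell_{di}}$, $p_{\mathrm{waic}} = \sum_i
\mathrm{Var}_d(\ell_{di})$ (sample variance), $\mathrm{WAIC} =
-2(\mathrm{lppd} - p_{\mathrm{waic}})$, with standard errors from the
pointwise contributions ($2\sqrt{n \,\mathrm{Var}_i}$). LOO uses
Pareto-smoothed importance sampling: the upper tail of the raw ratios
$1/p(y_i \mid \theta_d)$ is replaced by quantiles of a generalized
Pareto distribution fitted with the Zhang–Stephens quasi-Bayesian
estimator (weakly informative shape prior), smoothed weights truncated
at the raw maximum; the fitted shape $\hat k$ is reported per
observation and values above 0.7 flag an unreliable approximation. The
tests verify PSIS-LOO against exact leave-one-out re-integration on a
grid posterior at $n = 20$.

Pairwise comparisons use the asymptotically normal elpd difference with
SE from the pointwise differences, two-sided normal p-values, and
Bonferroni correction over the number of distinct pairs in the call (the
correction family was unspecified; all pairs of the comparison at hand is
the conservative, self-contained choice).

## What the synthetic generator emulates

The generator's defaults reproduce the structure of a six-year
province-scale study of 188 municipalities:

* **Lattice** — 188 areas in three contiguous subareas of 53/58/77 on a
  jittered rectangular grid with rook contiguity plus randomly retained
  diagonal edges (degree irregularity). Subareas are consecutive
  segments of a snake path, which guarantees contiguity and exact sizes.
  A Voronoi tessellation would mimic municipal polygons even better, but
  no computational-geometry package is available to the package's
  dependency set, and the contiguity *graph* — the only thing the models
  see — is equally well served by the irregular grid.
* **Urbanisation** — 28 urban units in two compact clusters (a capital
  and a secondary town with hinterlands), 28 peri-urban in rings around
  them, 132 rural: 160/188 non-urban.
* **Population** — 535,666 residents, 48.28% male, log-normal area sizes
  with the dominant area pinned at 12.8% of the total (the capital's
  share), an aging-skewed age profile over 20 classes, and the population
  held constant across years (a fixed reference-year population).
* **Exposure** — annual means 17.5–23.6 µg/m³ and SDs 5.1–6.5 matching
  the study period's published summaries year by year; one latent
  surface (north–south gradient + a low-frequency Gaussian field built
  by 40 neighbour-averaging passes of white noise) rescaled exactly to
  each year's mean/SD, floored at 0.5 µg/m³. `spatial_range` mixes the
  structured surface with white noise: 0 gives spatial independence,
  the default 8 gives Moran's I ≥ 0.90 on the 188-area lattice. The
  lattice itself caps Moran's I of any smooth field near 0.92 (its
  largest Moran eigenvalue is ≈ 1.12 and its diameter is smaller than a
  real municipal map's), so the emulation targets "strong positive
  autocorrelation", not the exact real-map value near 0.95.
* **Outcomes** — stratum-level deaths from the same log-linear model the
  package fits, with an age-risk profile rising exponentially across age
  classes (log-slope 0.35/class, female offset 1.15) scaled so the crude
  rate is ≈ 4.5/1000 — the scale of the published crude-rate table; the
  profile itself is not published and is a package choice. Optional IID
  / ICAR / BYM heterogeneity with chosen SDs; the full truth block
  (coefficients, random effects, per-area-year true RR) is stored for
  recovery tests.

What it does **not** emulate: real municipal geography and polygon
shapes, the spatial apportionment of gridded concentration products, the
population-grid computation behind urbanisation labels, migration or
population change over time, and any within-area (individual-level)
structure — so passing tests demonstrate the correctness of the
estimators and the pipeline on data satisfying the models' assumptions,
not robustness to the violations real registers exhibit. One published
inconsistency is deliberately not emulated: the study period's
exceedance-frequency table prints percentages inconsistent with
$n = 188$ (e.g. 103 areas as 57.78%); `exceedance_summary` always
reports count/$n$.

## Numerical choices and problem sizes

Degenerate inputs: single-node lattices have empty adjacency; a constant
vector is a hard error in Moran's I (zero variance); `e = 0` is a hard
error wherever a log offset is needed; asymmetric adjacency files are
rejected, not repaired; death counts are capped at the stratum
population (a negligible truncation at realistic risks).

The test suite and the worked examples run at reduced scale chosen so the
Monte-Carlo error of each check is small against its margin: bundles of
24–40 areas over 2 years; 2 chains × 700–6,000 iterations; 20-replicate
recovery studies at 40 areas × 2 years with total population 2,000,000,
where the pooled estimator's Monte-Carlo SE (≈ 0.006 on the log-RR
scale) is well below the 0.02 recovery margin; permutation tests at
99–10,000 permutations. The full-scale reference configuration (188
areas, 6 years, 4 × 10,000 iterations) runs unchanged but takes
correspondingly longer — the ICAR spectral basis costs one dense
eigendecomposition of the 188 × 188 Laplacian, and the BYM variance
parameters are the slowest-mixing quantities.

## Known limitations

* The ICAR spectral representation costs $O(n^3)$ once and $O(n^2)$ per
  deterministic update in the sampler; for lattices beyond a few
  thousand areas a sparse-precision sampler would be preferable.
* JAGS's samplers, even with the `glm` module, mix more slowly than
  gradient-based HMC on the BYM variance hyperparameters; the
  $\widehat R$ gate will flag short chains rather than hide this.
* Space-time interaction random effects, Leroux/BYM2 parameterisations
  and exposure measurement-error models are out of scope.
* The "no trend" and "subareas not different" verdicts are interval
  rules, not decision-theoretic tests; the full posterior tables are
  returned for users who want different rules.
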