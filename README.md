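# arealrisk

Spatio-temporal Bayesian disease mapping for small-area studies of
mortality and environmental exposure.

Epidemiologists who work with administrative areal units (municipalities,
districts) face a standard problem: raw standardised mortality ratios
(SMRs) in small populations are dominated by Poisson noise, producing
"leopard spot" maps that are impossible to interpret. `arealrisk`
implements the standard Bayesian answer end to end — hierarchical Poisson
log-linear models whose random components borrow strength across the
contiguity graph — together with everything around it: indirect
standardisation, spatial autocorrelation testing, descriptive conjugate
models, predictive model comparison, exceedance-probability risk maps,
and a seeded synthetic-data generator that emulates a province-scale
study (188 municipalities in 3 subareas, ~536k residents, six years of
cardiovascular deaths, a smooth PM2.5 exposure field), so the whole
pipeline is testable without access to a mortality register.

## The model

Deaths in area $i$, year $t$ follow
$y_{it} \sim \mathrm{Poisson}(e_{it}\,\theta_{it})$ with expected counts
$e_{it}$ from indirect age–gender standardisation
($\mathrm{Risk}_j = \sum_i \mathrm{Count}_{ij} / \sum_i \mathrm{Population}_{ij}$,
$e_i = \sum_j \mathrm{Population}_{ij}\,\mathrm{Risk}_j$) entering as an
offset:

$$\log \mu_{it} = \beta_0 + \beta_{pm}\,\mathrm{pm}_{it} + \beta_r\,\mathrm{rural}_i
+ [\beta_y (t - t_0)] + u_i + v_i + \log e_{it}$$

where PM2.5 is centred and scaled by 15 µg/m³, $u_i$ is an exchangeable
(IID) area intercept, and $v_i$ an intrinsic CAR (ICAR) effect on the
binary contiguity graph; $u + v$ is the Besag–York–Mollié (BYM)
convolution. Crossing {none, IID, ICAR, BYM} with {no trend, linear
trend} gives the eight-model grid (`make_model_grid()`), fitted by MCMC
(JAGS backend, ICAR sampled exactly in the graph-Laplacian spectral
basis) in four phases with informative-prior propagation. Models are
compared by WAIC and PSIS-LOO from per-observation log-likelihood draws;
per-area relative risks are classified *high* / *low* by the exceedance
probability $PP = P(RR > 1)$ against the 0.90/0.10 rule.

## Worked example

Simulate a 40-area, two-year study with a known exposure effect
(RR 1.075 per 15 µg/m³) and IID area heterogeneity (SD 0.15), then
standardise, test spatial autocorrelation, fit two of the grid models
and compare them:

```r
library(arealrisk)

b <- simulate_bundle(n_areas = 40, subarea_sizes = c(12, 13, 15),
                     years = 2010:2011, total = 535666,
                     beta_pm = log(1.075), re_kind = "iid",
                     re_sd = c(iid = 0.15, icar = 0.1), seed = 2024)

std <- compute_expected_counts(b$population, b$deaths_strata)
smr <- smr_table(std, b$population)

x <- dplyr::arrange(dplyr::filter(b$exposure, year == 2010), area_id)$pm25
morans_mc_test(x, b$lattice, n_sims = 999, seed = 1)
#>   i_stat  p_mc n_sims     e_i
#>    0.769 0.001    999 -0.0256

d <- build_design(b)
grid <- make_model_grid()
f1 <- fit_model(d, grid[grid$grid_id == "M1A", ], chains = 2, iter = 3000, seed = 7)
f2 <- fit_model(d, grid[grid$grid_id == "M2A", ], chains = 2, iter = 3000, seed = 7)

tidy(f2, exponentiate = TRUE)
#>   term      estimate std.error conf.low conf.high    pp  rhat
#>   intercept    0.863    0.0701    0.754     0.992 0.02   1.00
#>   pm25_c       0.900    0.108     0.727     1.13  0.163  1.00
#>   rural        1.16     0.0901    0.971     1.38  0.951  1.00

cmp <- compare_models(list(M1A = compute_waic(f1$draws$loglik),
                           M2A = compute_waic(f2$draws$loglik)))
cmp$criteria
#>   model criterion estimate    se  elpd p_eff
#>   M2A   waic          533.  16.7 -266.  19.8
#>   M1A   waic          613.  45.6 -306.  13.1

risk <- summarize_rr(f2)
dplyr::count(risk, class)
#>   class       n
#>   high        6
#>   low        17
#>   neutral    57
```

Reading the output: the exposure field is strongly spatially
autocorrelated (Moran's I = 0.769; none of 999 permutations reached it);
the M2A posterior rate ratio for PM2.5 is 0.90 with 95% credible
interval [0.73, 1.13] — at this deliberately small scale the interval is
wide and covers the generative truth of 1.075; the IID-intercept model
M2A beats the no-random-effect model M1A by ~80 WAIC points, exactly the
behaviour heterogeneous data should produce; and 6 of 80 area-years are
flagged high-risk (PP > 0.90). `autoplot(risk, b$lattice)` draws the
binned RR choropleth; `run_pipeline()` chains all stages (simulate →
standardise → Moran → descriptive models → eight-model grid with prior
propagation → comparison → risk maps) into one reproducible, seeded run
whose outputs carry a config hash.

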