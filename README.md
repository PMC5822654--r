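# activnet

Network autocorrelation analysis of children's accelerometer-measured
physical activity within school friendship networks.

## The problem

When children name their closest friends, outcomes such as daily
moderate-to-vigorous physical activity (MVPA) and sedentary time are
correlated across the resulting network: friends resemble friends. Ordinary
regression ignores this dependence and cannot answer the question of
scientific interest — *how strongly does activity travel through the
friendship structure?* `activnet` is for epidemiologists and quantitative
social scientists analysing sociometric cohort data of this kind
(friend-nomination rosters plus per-child outcomes and covariates), and for
methodologists who want a tested, self-contained implementation to simulate
against.

## The model

The core is the network autocorrelation (spatial lag) model

> y = ρ W y + Xβ + ε,  ε ~ N(0, σ²I)

where W is the directed friend-nomination adjacency matrix, row-standardised
so each non-zero row sums to 1 — so (Wy)ᵢ is the mean outcome of child i's
friends — and ρ is the network dependence. Estimation is by maximum
likelihood on the profile likelihood in ρ, with the log-determinant
log|det(I − ρW)| evaluated through per-school-block eigenvalues of W.
Covariate effects are decomposed via M = (I − ρW)⁻¹ into **direct** (mean
diagonal of M), **total** (mean row sum of M) and **indirect** (total −
direct) impacts, with percentile CIs from 200 parameter draws. Around the
model sit: accelerometer epoch processing (≥60-min zero-count non-wear
windows with ≤2-min interruptions, intensity cut points, 500-min valid
days, ≥3-day child summaries), Moran's I diagnostics with permutation
inference, cluster-robust OLS baselines, chained-equations multiple
imputation with Rubin's-rules pooling, and a synthetic cohort generator so
everything runs offline.

See the methods vignette (`vignettes/network-activity-models.Rmd`) for the
full account.

## Worked example

Simulate a small two-sex cohort (8 schools, ~200 children, no missing data)
and run the full analysis:

```r
library(activnet)
cfg <- run_config(
  sim = sim_config(n_schools = 8, children_per_school = 25, seed = 42),
  missingness = FALSE, n_perm = 999, n_sims = 200, seed = 42)
res <- run_study(cfg)
print(res)
#> Friendship-network activity analysis
#>   stratum F: 118 children, 298 ties
#>     mean_mvpa: rho = 0.206, AIC (network - OLS) = -1.6
#>     mean_sedentary: rho = 0.148, AIC (network - OLS) = 0.5
#>   stratum M: 82 children, 216 ties
#>     mean_mvpa: rho = 0.128, AIC (network - OLS) = 1.1
#>     mean_sedentary: rho = 0.209, AIC (network - OLS) = -0.3
```

Each line reports, per sex stratum and outcome, the estimated network
dependence ρ̂ and the AIC difference between the network model and the
cluster-robust OLS baseline (negative favours the network model). Drill
into one analysis:

```r
a <- res$strata$M$analyses$mean_mvpa
print(a$moran_resid)
#> Moran's I = 0.1537 (expectation -0.0123 under no autocorrelation)
#>   one-sided p = 0.028 (permutation, 999 permutations), n = 82
print(a$network)
#> Network autocorrelation model, n = 82, AIC = 711.7
#>   network dependence rho = 0.128 (95% CI -0.137 to 0.393)
#>                coefficient     se    lower   upper
#>                     0.1277 0.1353  -0.1375  0.3929
#> intercept         -20.8151 6.0592 -32.6908 -8.9393
#> imd                -0.0216 0.1922  -0.3983  0.3550
#> bmi_z              -3.1747 1.9035  -6.9054  0.5561
#> activity_score      3.9543 0.8646   2.2598  5.6488
```

The residual Moran's I of 0.154 (p = 0.028) says the baseline OLS residuals
are still autocorrelated over the boys' network, so modelling the
dependence is warranted; the lag model then attributes ρ̂ = 0.13 of that
structure to transmission through ties. The impact table splits each
coefficient into own-child and spillover parts:

```r
print(a$impacts)
#>       covariate direct indirect  total
#>             imd -0.022   -0.003 -0.025
#>           bmi_z -3.180   -0.459 -3.640
#>  activity_score  3.962    0.572  4.533
```

A one-point higher activity participation score raises a child's own MVPA
by ≈4.0 min/day (direct) and their schoolmates' by a further 0.6 min/day
spread over the network (indirect). Setting `outdir =` in `run_config()`
additionally writes GraphML networks, weight-matrix triplets, Moran scatter
data, fit and impact tables, and a manifest; `inst/scripts/run_study.R` is
a thin command-line wrapper around the same function.

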