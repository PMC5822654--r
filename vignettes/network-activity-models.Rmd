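---
title: "Modelling physical activity in children's friendship networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling physical activity in children's friendship networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activnet)
```

## The scientific problem

Children's moderate-to-vigorous physical activity (MVPA) and sedentary time
are not independent across children: close friends tend to resemble each
other. When each child in a school cohort names up to four closest friends,
the resulting directed friendship network induces dependence between
outcomes that ordinary regression ignores, biasing coefficients and — more
importantly — leaving the scientific quantity of interest, the strength of
transmission through the network, unestimated.

`activnet` implements the full analysis chain for this situation:
accelerometer processing, network construction, autocorrelation diagnostics,
the network autocorrelation model with impact decomposition, and multiple
imputation, together with a synthetic-data generator that emulates a
plausible cohort (roughly 47 schools and 1200 children aged 8–9) so the
entire pipeline runs, and is tested, without access to any restricted data.

## The model

The central model is the network autocorrelation model (also called the
network effect or spatial lag model):

$$ y = \rho W y + X\beta + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma^2 I), $$

where $y$ is the vector of per-child mean MVPA (or sedentary) minutes per
day, $X$ holds an intercept, the IMD deprivation score, BMI z-score and a
0–12 activity participation score, and $W$ is the friendship weight matrix:
$w_{ij} > 0$ exactly when child $i$ nominated child $j$, row-standardised so
every non-zero row sums to 1. Thus $(Wy)_i$ is the mean outcome of $i$'s
friends, and $\rho$ (the *network dependence*) measures how strongly a
child's outcome moves with their friends'.

Estimation is by maximum likelihood. Writing $A(\rho) = I - \rho W$, the
log-likelihood is

$$ \ell(\rho, \beta, \sigma^2) =
   -\tfrac n2 \log(2\pi\sigma^2)
   - \frac{\|A(\rho)y - X\beta\|^2}{2\sigma^2}
   + \log|\det A(\rho)|, $$

and concentrating $\beta$ and $\sigma^2$ out leaves a one-dimensional
profile likelihood in $\rho$ whose log-determinant term is evaluated through
the eigenvalues of $W$: $\log|\det A(\rho)| = \sum_i \log|1 - \rho\lambda_i|$.
Because nominations are confined within schools, $W$ is block-diagonal by
school and the eigenvalues are computed per block and cached — exact and
fast even for cohort-sized matrices. For a directed $W$ the eigenvalues may
be complex; the sum uses complex moduli, while the feasible interval for
$\rho$, $(1/\lambda_{\min}, 1/\lambda_{\max})$, is formed from the real
eigenvalues only and intersected with $(-0.999, 0.999)$. The maximiser is
found by a coarse grid (101 points) followed by Brent-style bounded search
at tolerance $10^{-8}$; a solution within $10^{-4}$ of the interval boundary
is flagged as not converged rather than silently returned.

The asymptotic covariance of $(\rho, \beta)$ comes from the negative inverse
of a numerical Hessian of the full log-likelihood at the optimum (we verified
the finite-difference Hessian against Richardson extrapolation and against
the profile-likelihood curvature; agreement is to six significant figures).

### Interpreting coefficients: impacts

Because $y = A(\rho)^{-1}(X\beta + \varepsilon)$, a unit change in covariate
$k$ for every child shifts the outcome vector by $M\beta_k$ with
$M = (I - \rho W)^{-1}$: each child's outcome responds both directly and
through friends-of-friends feedback. We summarise with the standard
averaging convention:

* **direct** impact $= \beta_k \cdot \operatorname{mean}(\operatorname{diag} M)$
  — the average own-child effect, feedback included;
* **total** impact $= \beta_k \cdot \operatorname{mean}(\text{row sums of } M)$;
* **indirect** ("spillover") $=$ total $-$ direct, exactly.

For a row-stochastic $W$ with no zero rows the total reduces to
$\beta_k / (1-\rho)$ in closed form, which the tests exploit as an oracle.
Confidence intervals are percentile intervals over 200 draws of
$(\rho, \beta)$ from the fit's multivariate-normal approximation; draws with
infeasible $\rho$ are discarded and counted, and more than 50% infeasible is
treated as evidence of misfit, not silently tolerated.

## Diagnostics: Moran's I

Before and after fitting, autocorrelation is quantified by Moran's I on the
outcome and on the baseline-model residuals,

$$ I = \frac{n}{S_0}\,
   \frac{\sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar x)}
        {\sum_i (x_i - \bar x)^2}, $$

with expectation $-1/(n-1)$ under no autocorrelation. Children whose weight
row is entirely zero carry no neighbourhood information; they are excluded
from $n$, $S_0$ and the mean by subsetting both $x$ and $W$ — the only
internally consistent reading, since a dropped child can then neither lend
nor borrow a neighbour value. Inference defaults to a one-sided permutation
test (999 permutations, $p = (1 + \#\{I_{perm} \ge I_{obs}\})/(n_{perm}+1)$);
the analytic normal approximation under randomisation is available as an
option. Under multiple imputation the residual I is computed per completed
dataset and summarised by its median and the fraction of datasets
significant at 0.05, since no single pooling rule for Moran statistics is
canonical.

## Accelerometer processing

Raw input is a count per 10-second epoch. Processing follows the standard
child-accelerometry conventions:

* **Non-wear**: every maximal window of total length ≥ 60 min consisting of
  zero counts is excluded, allowing interior interruptions — consecutive
  nonzero runs of ≤ 2 min are absorbed; a longer nonzero run terminates the
  window. We read the interruption allowance as *consecutive* (the usual
  Troiano-style convention) rather than cumulative; windows begin and end on
  zero epochs. A brute-force scan over all candidate windows serves as the
  test oracle.
* **Intensity**: counts-per-minute thresholds (defaults: sedentary ≤ 100
  cpm, moderate ≥ 2296 cpm, vigorous ≥ 4012 cpm, the child-specific cut
  points from the calibration literature) are scaled to the epoch length —
  cpm/6 for 10-s epochs, flooring ceilings and ceiling-ing floors so the
  per-epoch rule is never more permissive than the per-minute rule. Both
  boundaries are closed: a count at the scaled sedentary ceiling is
  sedentary, one at the scaled moderate floor is MVPA.
* **Validity**: a day is valid at ≥ 500 wear minutes; a child's means are
  defined at ≥ 3 valid days, otherwise flagged missing and later multiply
  imputed. Sedentary + light + MVPA minutes always equal wear minutes
  exactly. No weekend-day requirement is imposed for validity.

## Network construction

Nominations (up to four per child, within school and year) are matched to
the roster; out-of-study nominees are dropped with a count report. Analysis
is restricted to same-sex networks: opposite-sex ties are removed (reported
as a count and fraction), then children left without any in-study same-sex
tie are pruned — iterated to a fixpoint, though removing a degree-zero node
can never orphan a neighbour, so one pass suffices. $W$ is directed (a
nomination is a directed tie; mutual nominations give two entries and are
not symmetrised, though a `symmetrise` flag exists), binary before
standardisation, and block-diagonal under school ordering.

## Missing data

Multiple imputation uses chained equations ("regression switching"): 20
completed datasets, 20 cycles each, run separately by sex. Each variable
with missing values is imputed from a normal-linear regression on all other
modelled variables plus school indicators, with Bayesian parameter draws
(scaled inverse-chi-squared for the variance, normal for the coefficients)
so that both parameter and residual uncertainty propagate. The four 0–3
activity items are rounded and bounded after drawing; the 0–12 activity
participation score is *passively* recomputed as the item sum in every
dataset, never imputed directly. Observed cells are never altered — the
tests assert bit-equality. Downstream fits (including $\rho$, treated like
any coefficient) are pooled with Rubin's rules:
$\bar q$, $T = \bar W + (1 + 1/m)B$, and the small-sample degrees of
freedom $(m-1)(1 + \bar W/((1+1/m)B))^2$. Nominations are never imputed, so
the network is fixed across imputations. Under MI the impact intervals stack
the percentile draws across completed datasets, which folds
between-imputation spread into the percentile interval.

## The synthetic-data generator

The generator defines the study conditions the pipeline is tested under:

| Quantity | Default | Why |
|---|---|---|
| Schools × children | 47 × 20–32 (~1220) | cohort shape being emulated |
| P(female) | 0.55 | observed sex split |
| Nominations per child | uniform on {2, 3, 4}, max 4 | median of 3 named friends |
| Same-sex tie probability | 0.90 | ~10% of ties are opposite-sex |
| IMD | Gamma(mean 15, SD 10) | right skew typical of deprivation indices |
| BMI z | N(0.3, 1) | slightly above-reference cohort |
| Activity items | uniform {0..3} ×4 | score spans 0–12 |
| $\rho$ (MVPA) | 0.20; $\beta$ = (−15, 0, −2.5, 2.5); $\sigma$ = 15 | magnitudes typical of reported MVPA models |
| Sedentary | $\rho$ 0.12, $\beta$ = (20, 0.15, 2, −3.8), $\sigma$ = 40 | weaker dependence, larger scale |
| School random intercept SD | 5 min/day | makes cluster adjustment consequential |
| Missingness | 0.5% (BMI z) to 18% (sedentary), MAR | reported range of missing data |

Outcomes are drawn from the exact reduced form
$y = (I - \rho W)^{-1}(X\beta + u + \varepsilon)$ — solved per school block,
never truncated — with school random intercepts $u$. Generated outcome
scales are shifted (+60 MVPA, +420 sedentary min/day) to plausible
non-negative levels; the shift is absorbed by the intercept and leaves
$\rho$ and the slopes untouched. The MAR mechanism is logistic in sex and
the leave-one-out school mean of the outcome (leave-one-out so that
missingness never depends on the deleted value itself), with the intercept
calibrated by root-finding so realised rates match their targets. Epoch
series can be synthesised whose processed summaries reproduce the
model-generated outcomes to within 10-s rounding, letting the whole chain —
counts to pooled $\rho$ — run end to end; at full cohort scale this is slow
in pure R, so epoch synthesis is opt-in and demonstration-sized.

What the generator does *not* emulate: tie-formation dynamics (no
activity-based homophily — the analysis models outcomes given the network),
raw tri-axial accelerations, day-to-day within-child outcome variance
(per-day epochs are drawn around the child's mean; the within-child
variance of real accelerometry is a free design parameter we fixed at the
intensity-mix level), out-of-school friendships, and MNAR missingness.
Passing tests therefore show the estimator and pipeline are correct under
the stated model, not that real cohort estimates would be unbiased —
notably, the literature documents mild *underestimation* of $\rho$ in these
models, which our recovery experiments reproduce.

## Calibration experiments and numerical choices

The replicated calibration experiments (parameter recovery, CI coverage,
Moran test size/power) run at n = 600 children in 24 schools per stratum —
the approximate size of one sex stratum — with 100–200 replicates, sizes
chosen to keep Monte-Carlo error well inside the tolerance bands. Two
deliberate choices:

* they generate with **school random intercept SD 0**, because the fitted
  model contains no school effect and the networks are entirely
  within-school: a school intercept would be partially absorbed into
  $\rho$, so the experiment would confound estimator calibration with model
  misspecification. The study-scale default keeps SD 5 precisely so that
  the cluster-robust baseline matters.
* the generating $\beta$ for recovery experiments is (−15, −0.5, −2.5, 2.5)
  — a nonzero IMD effect — because relative (±5%) recovery tolerances are
  meaningless around a true zero.

Other numerical conventions: ties at intensity boundaries classify by the
closed-boundary rule above; eigenvalue caches live on the weight-matrix
object; degenerate inputs (zero-variance outcomes, empty networks,
rank-deficient designs, 100%-missing variables, infeasible $\rho$) raise
informative errors rather than propagating NaNs; all generation and
inference is a pure function of the supplied seeds.

## Known limitations

* The per-school eigendecomposition assumes $W$ is block-diagonal by
  school, which the constructors guarantee; a hand-built cross-school $W$
  would need the single-block path (one school label).
* The cluster-robust adjustment applies to the OLS baseline; the network
  model reports model-based asymptotic SEs (a cluster bootstrap is a
  natural extension, not yet implemented).
* Moran's I pooling under MI (median + fraction significant) is a reporting
  convention, not a formal combined test.
* Name-matching of free-text nominations is out of scope: nominations must
  arrive as resolved ids.
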