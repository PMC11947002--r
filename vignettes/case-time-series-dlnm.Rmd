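---
title: "Case time-series DLNMs for temperature and health: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case time-series DLNMs for temperature and health: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casetemps)
```

## The problem and the model

Short-term associations between daily temperature and acute health
events (here: mental and behavioral disorder emergency department
visits) are non-linear in temperature and distributed over several
days of lag. `casetemps` implements the small-area *case time-series*
design: every small geographic zone (e.g. a ZIP Code Tabulation Area)
contributes its own daily count series, and fine zone-by-year-by-month
strata absorb all time-invariant and slowly varying zone-level
confounding. The conditional model for counts $Y_{ijk}$ in zone $j$ on
day $i$ of period $k$ is

$$
\log E(Y_{ijk}) = \alpha
 + cb(\mathrm{Temp}_{ik})
 + ns(\mathrm{RH}_{ik},\, df_1)
 + ns(doy_i,\, df_2)\cdot\mathbf{1}(year_k)
 + \textstyle\sum_{l=1}^{7}\beta_l\,\mathbf{1}(DOW_{ik}=l)
 + \gamma_{j,\,year,\,month},
$$

where $cb(\cdot)$ is a temperature-by-lag cross-basis over lags 0–7
days, $ns(\cdot)$ are natural cubic splines ($df_1 = 2$ for relative
humidity, $df_2 = 3$ for day-of-year, one spline copy per year so
seasonal shape can differ across years), day-of-week indicators use
Sunday as reference, and $\gamma$ are the strata. $\alpha$ and
$\gamma$ are not separately identifiable; both are absorbed by the
conditional (profiled) likelihood and deliberately not reported.

Estimation is conditional quasi-Poisson: the Poisson likelihood with
stratum intercepts profiled out,
$\hat\alpha_s = \log(Y_s / \sum_{i\in s} e^{\eta_i})$, maximized by
Newton iterations in which covariates are mean-centered within strata
using the current weights. The coefficient vector is identical to a
Poisson regression with one explicit dummy per stratum (the package's
central test verifies this to $10^{-6}$ against `glm`), but absorbing
the strata scales to hundreds of zones times 48 months without
materializing thousands of dummy columns. Standard errors are scaled
by the Pearson dispersion $\hat\phi = \chi^2_P / (n - p - S)$, with
$S$ the number of informative strata.

## The cross-basis

The cross-basis columns are products
$W_{t,(j,k)} = \sum_{l=0}^{7} R_j(x_{t-l})\, C_k(l)$ of a natural
cubic spline $R$ over temperature and a natural cubic spline $C$ over
lag. Defaults:

* **Exposure dimension**: interior knots at the 25th/50th/75th
  percentiles of the temperature series the basis is resolved against,
  boundary knots at its range, no intercept (absorbed by the strata).
  The published description of the exposure-dimension knots is
  ambiguous (it conflates exposure and lag placement); percentile
  placement is the standard DLNM default and is configurable through
  `spline_spec()`, including equally spaced knots if preferred.
* **Lag dimension**: one interior knot at lag 1, knots placed on the
  $\log(l+1)$ scale over the window 0–7, giving more flexibility at
  short delays, **with** an intercept column. The lag intercept
  deserves a note: natural-spline bases evaluate to zero at their left
  boundary knot, so a lag basis *without* an intercept would force the
  fitted same-day (lag 0) effect to be exactly zero — a substantive
  restriction, not a harmless normalization. The products
  $R_j(x)\cdot C_0(l)$ with $C_0 \equiv 1$ are moving averages of the
  exposure basis, genuine covariates that the strata do not absorb.
  Validation runs with the intercept omitted showed exactly the
  expected attenuation of cumulative effects, which is why the
  intercept is on by default.
* **Column ordering**: exposure index fastest; the convention is
  stored in the serialized spec (`cb_spec_to_json()`) so coefficient
  vectors are portable across fits and into pooling.
* **Incomplete lag histories**: the first 7 days of each zone are
  flagged and dropped from the likelihood (standard time-series DLNM
  practice) rather than imputed; lagging never crosses zone
  boundaries.

Reported quantities reduce the fitted surface over the lag window: the
overall cumulative log relative risk at temperature $x$ against a
reference $x_0$ is $a(x)^\top\beta_{cb}$ with
$a(x) = [R(x) - R(x_0)] \otimes s$, $s_k = \sum_l C_k(l)$, standard
errors by the delta method, 95% intervals with the normal 1.96
multiplier. The reference is the median temperature; `rr_at()`
evaluates the contrast at the 2.5th and 97.5th percentiles, and the
minimum-risk temperature is the grid argmin of the curve (200 grid
points between the basis boundaries, about 0.2 °C resolution for a
typical statewide range; exact ties break toward the colder
temperature). Grids beyond the basis boundary are refused rather than
silently extrapolated along the linear tails.

Percentile anchors use the linear-interpolation sample quantile
(R type 7) throughout. Fits use absolute temperature; for region- or
state-level reporting the anchors come from the pooled day-weighted
temperature distribution of that region or the state, with per-zone
anchoring available — the published analysis computes percentiles per
zone but reports single region RRs, so the pooled-anchor choice is an
interpretation, not a claim about the original.

## Pooling across regions

Region-specific cross-basis coefficient vectors are combined by
multivariate fixed-effect inverse-variance pooling,
$\beta_p = (\sum_r V_r^{-1})^{-1} \sum_r V_r^{-1}\beta_r$. Pooling is
only defined on a shared basis, so the pipeline resolves one statewide
knot set whenever pooling is requested and refuses mismatched basis
fingerprints. A random-effects variant (`pool_random_mm()`) estimates
the between-region covariance by a weighted moment estimator (solving
$E[\sum_r W_r d_r d_r^\top] = \sum_r M_r V_r + (\sum_r M_r)\Psi$ with
$M_r = W_r - W_r S^{-1} W_r$, symmetrized and eigenvalue-truncated to
positive semi-definite); in one dimension it reproduces the classical
DerSimonian–Laird estimate exactly. Fixed-effect pooling is the
default: three regions are too few for a stable between-region
covariance. With three regions the state row is better served by a
single statewide fit, which is the pipeline default
(`state_mode = "statewide"`); pooling is retained for sensitivity
analysis.

## The synthetic-data generator

Real analyses of this design rest on confidential line-level ED data
and licensed gridded weather, so the package carries a first-class
generator whose defaults are the study conditions used by every
validation experiment:

| parameter | default | why |
|---|---|---|
| regions | Mountains/Piedmont/Coast, zone shares 1:3:2 | three physiographic regions, central region largest |
| annual mean temperature | 13.5 / 16.3 / 17.6 °C | published regional climatology |
| seasonal amplitude | 12 °C (peak ~July 20) | with AR(1) noise gives a marginal SD ≈ 9.2 °C, matching the printed statewide SD of 8.89 °C |
| AR(1) $\rho$, innovation SD | 0.7, 2.5 °C | realistic day-to-day persistence of temperature anomalies |
| dewpoint depression | mean 5 °C, SD 3 °C, truncated at 0 | relative humidity ≈ 70%, and dewpoint ≤ temperature always, so derived RH ≤ 100% |
| baseline rate | 5 visits/zone-day | statewide total visits over zones × days ≈ 5.1 |
| overdispersion | 1.5 | the source data's dispersion is unpublished; 1.5 is a mild, defensible default, flagged here as a free choice |
| stratum SD | 0.1 | zone-by-year-by-month log-baseline heterogeneity |
| day-of-week, seasonal log-rate | small offsets, 0.05 sinusoid | weekly and seasonal utilization patterns |

Counts are Poisson, or gamma-mixed Poisson (negative binomial with
`size = mu/(phi - 1)`, hence variance exactly $\phi\mu$) when
overdispersion is requested — quasi-Poisson only specifies a variance
function, and the gamma mixture gives a controllable dispersion
target, recovered by the fitted Pearson dispersion to within ±0.3 at
50,000 rows in the tests. The injected temperature effect is a
`TrueEffectSurface`: a cumulative log-RR function of temperature (zero
at its reference) distributed over lags 0–7 by non-negative weights
summing to one (default: geometric decay, rate 0.6). The first seven
days of each zone pad their missing lag history by repeating the first
temperature; the fitter instead drops those rows, and the two
conventions agree on long series where the edge is negligible.

Randomness is organized as one master seed from which two substreams
per zone (temperature, counts) are drawn; the substream seeds are a
prefix of one fixed stream, so enlarging `n_zones` never perturbs
existing zones, and identical configurations are bit-reproducible.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: spatial correlation of
temperature across zones (each zone's series is independent),
population mobility between zones, reporting delays, zone-level
population size differences, and exposure measurement error from the
area-weighted gridded aggregation. The validation experiments certify
the estimator, not the epidemiology.

## Validation experiments and their sizes

All experiments run on one CPU inside the test suite and the
acceptance script; sizes were chosen so the estimator is examined at
realistic scale while the whole suite stays comfortably inside a
coffee break.

* **Oracle equivalence** — 10 zones × 2 years (~7,300 rows): absorbed
  strata vs explicit `glm` dummies, coefficients to $10^{-6}$.
* **Parameter recovery** — 25 replicates of 100 zones × 4 years
  (146,100 rows each) with a linear exposure truth calibrated to a
  cumulative RR of 1.05 at the panel's 97.5th percentile. A linear
  truth lies inside the exposure-basis span, so the estimand equals
  the injected value. Pilot decomposition showed the estimator is
  unbiased when the generator's seasonal log-rate term is off (15
  replicates: mean 1.0485, MC se 0.004); with the full generator the
  df-3 day-of-year spline only approximates the seasonal sinusoid,
  leaving a residual of about −0.011 on the RR scale (50 replicates:
  mean 1.039) — inside the ±0.015 band, and a fair picture of what
  mild seasonal-model misspecification does to this estimator.
  Coverage over 25 replicates is compared to the scaled-down band
  [0.84, 1.00].
* **Type-I behaviour** — 100 replicates of a null surface at 15 zones
  × 2 years with overdispersion 1.5: the share of 95% intervals
  excluding RR = 1 must sit in [2%, 9%].
* **QAIC lag selection** — 30 replicates at 30 zones, AR(1) 0.3 and a
  strong (RR 1.8) effect whose lag profile lies exactly in the span of
  a 2-interior-knot lag basis: QAIC (computed with the richest
  candidate's dispersion; parameter count excludes the absorbed
  strata, which cancel in comparisons) must select the generating
  flexibility in ≥ 60% of replicates. Lag-profile information comes
  from day-to-day anomalies, hence the reduced autocorrelation in this
  experiment.

## Numerical choices and degenerate inputs

* Newton convergence: relative log-likelihood change below $10^{-9}$
  or 100 iterations, with step-halving; non-convergence is an error,
  never a silent result.
* Columns with within-stratum variance below $10^{-12}$ (e.g. a
  zone-level ICE value entered as a covariate) are dropped with a
  warning naming them; if collinearity survives into the information
  matrix the fit aborts with the column list. With monthly strata the
  seasonal interaction terms are retained as specified; they are
  estimable because day-of-year varies within month, but a generic
  fitter's silent column drops are replaced here by the explicit rule
  above.
* Strata whose counts are all zero contribute nothing to the
  conditional likelihood; they are dropped and counted.
* All-equal ICE values collapse the quartile cuts; ties at a collapsed
  boundary take the most advantaged label, so a degenerate vector is
  all Q1.
* Age bins are inclusive integer years, 0–25 / 26–49 / 50–64 / 65+;
  a 25-year-old belongs to the first bin (the source's two
  descriptions of this bin disagree; the Study-population coding
  wins).
* Zip-to-zone crosswalks may be many-to-one; one-to-many zips resolve
  to the largest-weight zone. How the original analysis resolved these
  is unstated; this rule is documented, deterministic, and total.
* Visit records outside F00–F99, or with unparseable codes, are
  excluded and counted in a message; parsing ignores everything after
  the decimal point.

## Subgroups

Diagnosis subgroups (substance F10–F19, mood F30–F39, anxiety
F40–F49) re-filter the line-level records; sex and age strata likewise;
community strata (ICE income/race quartiles, Q1 = most advantaged)
subset zones while keeping all F00–F99 visits — only the diagnosis
subgroups restrict the outcome. Basis knots are resolved once on the
full exposure panel and reused across subgroups for comparability
(whether the original re-estimated knots per subgroup is unstated).
Strata under 1,000 visits by default are reported as insufficient
rather than fitted — the original dropped individual-race strata for
low sample size without stating a cutoff. No multiplicity correction
is applied; per-cell 95% intervals are reported as-is, deliberately.

## A worked example

```{r example, fig.width = 6, fig.height = 4}
cfg <- sim_config(n_zones = 8, date_start = "2016-01-01",
                  date_end = "2017-12-31", seed = 7)
panel <- simulate_case_panel(cfg)
fit <- fit_conditional_quasipoisson(build_design(panel))
glance(fit)

anchors <- percentile_anchors(panel$tavg_c, source = "state")
rr_at(fit, anchors, c(2.5, 97.5))

curve <- cumulative_curve(fit, anchors)
autoplot(curve, anchors = anchors)
```

Under this null configuration the relative risks at both percentile
anchors should straddle 1, the dispersion should sit near the
generator's 1.5, and the curve's interval should widen toward the
sparse temperature extremes.

## Known limitations

The estimator assumes counts are independent across days given the
modelled terms; residual within-zone serial correlation beyond the
strata is not corrected (no autocorrelation-robust errors). Exact
conditional inference, penalized or random-effect variants, lag
windows beyond what memory comfortably holds as dense matrices, and
attributable-fraction summaries are out of scope. The pooled
random-effects variant is method-of-moments, not (RE)ML, and with
three regions its between-covariance is noisy — which is why it is not
the default.
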