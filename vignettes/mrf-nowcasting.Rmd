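---
title: "Joint prevalence nowcasting with Mahalanobis random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint prevalence nowcasting with Mahalanobis random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrfnowcast)
```

## The problem

Development and humanitarian agencies need cluster-level estimates of
poverty and malnutrition prevalence between (and beyond) expensive household
survey rounds. The unit of analysis here is the survey **enumeration area
(EA)**: a small cluster with anonymity-jittered coordinates, five prevalence
outcomes in $[0,1]$ (child stunting, child wasting, healthy child weight,
asset poverty, underweight women), and a vector of open geospatial
covariates. Two tasks are supported:

* **Sequential nowcasting** — predict a survey year's outcomes using only
  *earlier* surveys from the same country for training, plus current
  covariates. This is the early-warning use case.
* **Contemporaneous prediction** — predict held-out EAs of the current
  survey using prior rounds plus 80% of the current round (five-fold
  cross-validation). This is the poverty-mapping use case.

## The model

For survey $(t, c)$ (year, country) with outcomes
$y_i \in \mathbb{R}^5$ and features $x_i \in \mathbb{R}^p$ we assume a
signal-plus-noise model $y_i = f(x_i) + \varepsilon_i$ with
$\operatorname{Cov}(\varepsilon_i) = \Sigma$. The estimator of $f$ is a
multivariate random forest whose node splits minimise the **Mahalanobis
cost**

$$C_L = \sum_{i \in L} (y_i - \bar y_L)^\top \Lambda\, (y_i - \bar y_L),$$

where $\bar y_L$ is the componentwise mean in leaf $L$ and
$\Lambda = \Sigma^{-1}$ is the outcome precision matrix. Writing
$\Lambda = W^\top W$ (Cholesky), $C_L$ is exactly the per-dimension sum of
squared errors of the *whitened* outcomes $W y$: the criterion is the
ordinary variance criterion after decorrelating the outputs, so splits
jointly reduce variance across all five prevalences while exploiting their
dependence. With $k = 1$ outcome and any scalar $\Lambda > 0$ the learner
reduces split-for-split to a standard univariate regression forest (an
argmin is invariant to positive scaling); the test suite verifies this
against an independent plain-R implementation.

Terminal nodes predict the componentwise mean of the outcome vectors they
contain; the forest prediction is the across-tree average, and the
across-tree standard deviation of the per-tree predictions is reported as a
per-EA uncertainty measure for nowcast maps.

### Precision estimation (feasible GLS)

$\Sigma$ is unknown, so `estimate_precision()` proceeds as in feasible
generalised least squares: one univariate forest per outcome (same
hyperparameters) is fit to the training data, the training residuals
$y - \hat y$ are collected, $\hat\Sigma$ is their sample covariance, and
$\Lambda = \hat\Sigma^{-1}$ after a diagonal ridge
$\delta \cdot \overline{\operatorname{diag}(\hat\Sigma)}$ with
$\delta = 10^{-6}$, doubled until the condition number drops below $10^8$.
Residuals that are zero to float precision (a perfect in-sample fit) trigger
an identity fallback with a warning. The same univariate forests, evaluated
on the held-out rows, form the **independent random forest (IRF)** baseline,
always run on the same folds as the joint model.

### Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `trees` | 2000 | forest size $T$ |
| `max_depth` | 4 | maximum tree depth $d$ |
| `dsr` | 1/3 | per-node feature downsampling rate |
| `bootstrap` | TRUE | one bootstrap resample per tree |
| `min_leaf` | 2 | minimum rows per leaf |

$T$, $d$ and `dsr` defaults are the shared values selected upstream by
cross-validation for the survey application; re-running that search is out
of scope and the values are taken as configuration. Bagging and *per-node*
(rather than per-tree) feature subsampling follow standard random-forest
practice; both are exposed as toggles because the original description
fixes only the downsampling rate.

### Numerical choices

* Candidate thresholds are midpoints between consecutive distinct sorted
  feature values; a node refuses to split when no candidate reduces cost by
  more than $10^{-12}\max(1, C_\text{parent})$.
* Equal-cost candidates (e.g. two features inducing the same row partition)
  are resolved to the lowest feature index, then the lowest threshold; the
  comparison uses a $10^{-9}$ relative margin so the resolution is stable
  against the order in which prefix sums accumulate rounding error. The
  exhaustive-scan oracle tests rely on this being exact.
* The across-tree prediction variance uses the population ($1/T$) form so a
  single-tree forest reports zero spread; cancellation noise below
  $10^{-12}$ relative is clamped to zero.

## Feature construction

* **Static geography** (travel time, tree cover, pasture, altitude, slope)
  is matched to each EA by nearest great-circle distance
  (`assign_nearest_static()`), haversine on a 6371 km sphere.
* **Seasonal anomalies** (`seasonal_zscore()`): the 12 months before the
  survey start are split into four consecutive 3-month seasons *anchored to
  the survey date* (months $-3..-1$, $-6..-4$, $-9..-7$, $-12..-10$). For
  each season, $z$ = (mean value at the nearest sensed cell during the
  season − reference mean) / reference sd, where the reference pools every
  raw value within 100 km whose calendar month falls in that season, across
  the series' full record. The feature is the mean of the four $z$; a season
  with zero reference sd contributes $z = 0$ (flat regions never divide by
  zero). Survey anchoring makes the operation well defined for any start
  month; calendar-quarter seasons are available as a toggle. The sd uses the
  $n-1$ convention.
* **Food prices** (`price_window_features()`): per (market, commodity), the
  mean and sample variance of monthly prices over the 12 months strictly
  before the survey start; series missing any window month are excluded
  outright. Markets are ordered by distance, so the $n$-th feature block
  always belongs to the $n$-th nearest market. Prices keep their reported
  unit tag; no currency or unit conversion is attempted.
* **Conflict** (`conflict_window_counts()`): events lacking a georeference
  or timestamp are removed; the counts cover events starting in the year
  before the survey plus longer events whose end date falls in that window,
  each counted once, with deaths summed — country-specific but otherwise
  spatially agnostic.
* **Missingness filter** (`filter_missing()`), applied per test/train
  regime: drop features missing in strictly more than 20% of the regime's
  rows, then drop rows with any remaining missing feature or outcome.

## Evaluation

Out-of-sample $r^2_j = 1 - \mathrm{SSE}_j/\mathrm{SST}_j$ per outcome $j$,
with the baseline the scalar mean of the observed test outcomes of the
reporting unit (the printed form of the baseline carries an observation
index, but a per-observation baseline would zero the denominator, so the
pooled scalar mean — standard out-of-sample $r^2$ — is used). NRMSE is RMSE
divided by the observed outcome range of the reporting unit; because the
source description is ambiguous between the test-set and training-set
("in-sample") range, both are exposed (`range_source = "test"` default,
`"train"` alternative). Metrics are reported at three pooling levels —
aggregate, country, survey — plus size-weighted and unweighted country
means; the weighted mean uses pooled test-row counts per country, the most
natural reading of "relative survey size". In the contemporaneous regime
the score of a unit is the across-fold mean, with the across-fold standard
deviation alongside. Fold assignment is a seeded shuffle recorded in every
output.

MDI importance for a feature is the across-tree mean of
$\sum_{\text{splits on } x} (C_\text{parent} - C_\text{left} -
C_\text{right})/n_\text{tree}$, i.e. the fraction of the tree's samples
reaching the node times the per-sample cost decrease. Features are combined
into reporting groups (location, remoteness, vegetation, weather, market,
conflict, time) by summing member MDIs.

## The synthetic world

`generate_world()` builds a complete testbed: countries with bounding
boxes, survey rounds of a few hundred EAs with coordinates jittered
uniformly in a 10 km disc (a local-tangent approximation of the
anonymisation offset), three gridded monthly sources with seasonal
harmonics and interannual anomalies, market price panels, and conflict
events. Outcomes are generated as
$y = \mathrm{clip}_{[0,1]}\big(0.12 + 0.76\,\sigma(\eta) + \varepsilon\big)$
where $\eta$ is a linear-plus-one-interaction function of 4–6 standardised
covariates per outcome (scaled by a per-outcome signal strength, plus a
per-year drift) and $\varepsilon$ is multivariate normal with a configurable
covariance. The logistic is scaled into $[0.12, 0.88]$ so the noisy
prevalences rarely clip; the clip fraction is logged and kept below 1% at
the default noise level. Setting all signal strengths to zero makes the
pre-clip outcomes pure noise, which is how the tests verify covariance
recovery. Per-source sub-seeds are derived from the master seed by fixed
offsets, so adding or reconfiguring one source never perturbs another's
draws.

Default conditions (chosen once as a realistic small survey world): 3
countries × survey years 2008/2011/2014 × 200 EAs per survey, outcome noise
sd 0.05 with pairwise correlation 0.3, a 0.5° synthetic raster grid (the
real products' finer grids are upstream of this artifact), 5 markets × 3
commodities per country, ~20 conflict events per country-year. The per-year
drift of the link (default 0.3) is what makes contemporaneous prediction
genuinely easier than sequential nowcasting, mirroring the survey
application.

What the generator does **not** emulate: realistic spectra of the remote
sensing sources, DHS sampling weights, spatial autocorrelation of the
outcome noise, or changing EA frames between rounds beyond redrawing
locations. Passing tests therefore demonstrate correctness of the
machinery and qualitative behaviours (joint-estimation gain under
correlated noise, survey-size effects), not real-data performance levels.

## Problem sizes used by the checks

The test suite and the acceptance script scale the study conditions down so
a full run stays comfortable on one CPU: forests of 100–300 trees, worlds
of 1–3 countries with 40–800 EAs per survey, 20 seeds for the stochastic
recovery properties, and 5000 EAs for the covariance-recovery check. These
sizes are the package's own choices; the defaults above remain the survey
application's configuration.

## Known limitations

* One forest is fit per (country, test year, variant, fold); there is no
  pooling across countries and no spatial autocorrelation model.
* The split scan is exhaustive over midpoints; no histogram binning, so
  very large surveys pay $O(n \log n)$ per node per feature.
* NRMSE is undefined for a reporting unit with zero observed range, and
  $r^2$ for a constant-outcome unit; both are reported as missing with a
  warning rather than imputed.
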