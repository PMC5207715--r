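---
title: "Computing diversity-weighted multi-species abundance indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing diversity-weighted multi-species abundance indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpindex)
```

## The model

The Living Planet Index family of indicators summarises change in vertebrate
population abundance as a geometric mean across species, relative to a
baseline year. The unit of information is a monitored population: a sparse
time series of counts, densities or abundance proxies in arbitrary units.
The pipeline is:

1. **Population rates.** Each population's series is converted to annual
   rates of change on the log10 scale,
   $d_t = \log_{10}(N_t / N_{t-1})$.
   Series with at least six observations are smoothed first with a
   generalized additive model (GAM) of $\log_{10} N$ against year, and the
   rates are taken from the smooth evaluated in every year of the observed
   span. Shorter series (or series where the smooth fails) use the *chain
   method*: log-linear interpolation across gaps, then direct year-on-year
   ratios. Because units cancel in the ratio, the index is invariant to
   rescaling any population's series — a property the test suite asserts.

2. **Species trends.** Where a species has several populations, their
   annual rates are averaged arithmetically per year,
   $\bar d_t = \frac{1}{n_t}\sum_i d_{it}$,
   over the $n_t$ populations with a rate in year $t$.

3. **Hierarchical aggregation.** Two hierarchies are supported.
   *Unweighted* (LPI-U): species trends are averaged within the six
   zone-by-system subsets (tropical/temperate crossed with terrestrial,
   freshwater, marine); system trends are averaged equally within each
   zone; the two zone trends are averaged equally.
   *Diversity-weighted* (LPI-D): species trends are averaged within each
   system-realm-taxon group; taxon trends are combined within a realm with
   weights equal to each taxon's share of the known species of that realm;
   realm trends are combined within a system by the realm's share of known
   species; the three system trends are averaged equally.

4. **Index reconstruction.** The averaged rates become an index via
   $I_t = I_{t-1} \cdot 10^{\bar d_t}$ with $I_{1970} = 1$. Averaging
   always happens on the rate (log) scale and conversion to the index is
   the final step, which is what makes the species aggregation a geometric
   mean of abundance changes.

A note on the weighted average: at each weighted level the package computes
$\sum_j w_j \bar d_{jt}$ with the proportional weights $w_j$ renormalised
over the children that have data in year $t$. A formulation that both
divides by the number of groups and multiplies by proportion weights is not
a mean — it would not reduce to the plain average under equal weights — so
the renormalised weighted mean is used throughout, matching the
equal-weight special case and the hierarchical pseudocode convention.

## Tunable parameters

* `window` (years, default 1970–2012): the index period. Observations
  outside it are discarded and the two-observations-per-population rule is
  re-applied after truncation.
* `gam_min_points` (default 6): minimum observations for the GAM route.
  Below it the chain method is used.
* `cap` (log10 units/year, default 1): symmetric clip on annual rates,
  i.e. at most a tenfold change per year enters the averages. Clipping
  guards against census artefacts; `cap = Inf` disables it, which the
  closed-form validation tests rely on.
* `boot`, `level`, `seed`: bootstrap iterations (10,000 recommended for
  reporting; far fewer suffice for smoke tests), confidence level, and the
  seed that makes the resampling reproducible.

The GAM basis dimension is half the number of observations (minimum 3),
a smoothness budget that tracks series length without interpolating noise.
A fit is rejected — falling back to the chain method — if it errors, yields
non-finite values, or leaves the observed log10 range by more than one
order of magnitude. That "poor fit" screen is a documented package choice:
it is conservative, logged per population, and configurable in the sense
that the chain route can always be forced.

Zero abundances are valid observations but undefined under a log ratio, so
any series containing a zero is shifted by 1% of its mean observed value
before rate computation — the smallest-intervention convention in this
literature. All-zero series carry no trend information and are dropped with
a warning.

## Bootstrap confidence intervals

Uncertainty is estimated by resampling **species with replacement within
each lowest-level group** (zone-by-system subsets for the unweighted
hierarchy, system-realm-taxon groups for the weighted one) and recomputing
the whole aggregation per resample; per-year 2.5% and 97.5% percentiles
bound the 95% interval. Species is the unit because it is the first level
averaged; resampling within groups preserves group sizes, so the
proportional weights keep their meaning. Population-level rate estimation
is not repeated — the intervals express between-species sampling
uncertainty, not GAM smoothing uncertainty. The base year is pinned at 1,
so the interval has zero width there and widens along the series. The
percentile method is used rather than BCa, matching the practice this
methodology descends from; a consequence worth knowing is that the point
estimate is not mathematically guaranteed to lie inside the interval
(though in practice it essentially always does).

## Representation diagnostics

Taxonomic coverage is assessed per realm by comparing each taxon's share of
the species in the dataset with its share of the known species, via the
two-sample chi-squared test of proportions with Yates continuity correction
(`stats::prop.test`; the correction is toggleable because conventions
differ). Red List coverage compares the dataset's category proportions
(LC, NT/LR, VU, EN, CR) per taxon against reference proportions of assessed
species, optionally restricted to threatened species listed under the
population-reduction criterion (Criterion A) on both sides — the subset
whose listing implies declining abundance. No multiple-testing correction
is applied by default, matching the per-cell significance-star presentation
convention; printed chi-squared values from rounded input proportions are
not exactly recoverable, so validation asserts direction labels, not
statistics. Groups below a representation threshold (1% by default) can be
removed with `exclude_low_representation()` to probe their influence.

## The synthetic-data generator

`simulate_lpd()` draws datasets from a world of groups with known constant
annual multiplicative rates $r_g$: populations follow
$N_t = N_0 r_g^{\,t}$ with lognormal observation noise $10^\varepsilon$,
$\varepsilon \sim \mathcal N(0, \sigma)$ on the log10 scale — the natural
conjugate of a log10 rate, keeping expected rates unbiased. Initial
abundances are log-uniform on [10, 10,000] to exercise unit heterogeneity;
series lengths, start years and per-year missingness are configurable, with
the two-observation rule enforced. Defaults are fixed once: the full
1970–2012 window, noise sd 0.05 (a realistic count-survey error of roughly
12% per observation), no missingness unless requested.

Because every group's rate is constant, the expected index has a closed
form — the nested (weighted) arithmetic means of $\log_{10} r_g$,
cumulatively exponentiated — implemented independently in `true_index()`
and used as the oracle for pipeline validation: noiseless recovery to
1e-10, bootstrap coverage of the analytic truth under noise, and a
deterministic demonstration that diversity weighting reverses the sign of
a trend dominated by an over-monitored, atypical group.

What the generator does *not* emulate: trend autocorrelation, density
dependence, observation error that varies over time, within-group rate
heterogeneity, and spatial structure. Passing tests therefore show the
aggregation machinery is correct, not that real monitoring data meet the
model's assumptions.

## Problem sizes used in validation

The test suite validates bootstrap coverage with 100 simulated replicates
of a 200-species, two-group world (noise sd 0.05, full window, one
population per species) at 200 bootstrap iterations each, checking that the
95% interval for the final index covers the analytic truth in at least 90%
of replicates. Closed-form and oracle checks run on small worlds (tens of
species) where exactness, not power, is the point. The acceptance script
reruns the deterministic bias demonstration and a single 200-species
recovery, and converts published 2012 index values to average annual rates.

## Known limitations

* Weights are only as good as the species lists behind them; the package
  treats them as exact inputs.
* A year in which no group has data propagates a flat index (rate 0) with
  a warning rather than an error; sparse early years deserve inspection.
* The chain method distributes a multi-year change uniformly on the log
  scale across a gap, which understates year-to-year variance for gappy
  series.
* Confidence intervals omit smoothing and observation-model uncertainty.
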