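---
title: "Measuring community synchrony in percent-cover time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring community synchrony in percent-cover time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefsync)
```

## The model

A monitoring design observes a community of $k$ taxa at $S$ fixed plots
over $T$ annual surveys, recording each taxon's percent cover (fraction of
plot area, $\times 100$). Within one plot, let $N_i(t)$ be taxon $i$'s
cover in year $t$ and $v_{ij}$ the sample temporal covariance between taxa
$i$ and $j$. The synchrony index is

$$
\varphi \;=\; \frac{\sum_{ij} v_{ij}}{\bigl(\sum_i \sqrt{v_{ii}}\bigr)^2}.
$$

Because $\sum_{ij} v_{ij}$ is exactly the temporal variance of the
community total $\sum_i N_i(t)$, $\varphi$ compares observed total-cover
variability with the maximum attainable if every population fluctuated in
phase. $\varphi = 1$ under perfect synchrony; $\varphi = 0$ when the total
never fluctuates (perfect compensation). This identity is also the
package's internal oracle: tests verify, over randomized matrices, that
the implemented numerator agrees with `var(rowSums(m))` to $10^{-9}$
relative tolerance.

$\varphi$ alone cannot say whether an intermediate value reflects
biologically structured covariation or just finitely many randomly
co-fluctuating populations. Three resampling procedures address that.

### Permutation null for $\varphi$

Each replicate independently permutes every taxon's values across years
and recomputes $\varphi$. The permutation preserves each population's
multiset of values — hence its temporal variance, and the index
denominator — bit-exactly, so the null isolates the covariance structure:
it is the distribution of $\varphi$ for communities of randomly
co-fluctuating populations with the observed population-level variation.
The total-community variance is deliberately *not* held fixed from
replicate to replicate; only its population components are. Observed
values strictly below the central 95% quantile range of the null indicate
net negative covariation (compensatory dynamics); strictly above, net
positive covariation. Quantiles use linearly interpolated order statistics
(type 7), and equality with a bound is classified not-significant — a
conservative, deterministic tie rule.

### Permutation repeated-measures ANOVA

Year effects on total cover are tested with the one-way within-subjects
decomposition $SS_{total} = SS_{sites} + SS_{year} + SS_{error}$ on a
balanced site $\times$ year matrix, with
$F = MS_{year}/MS_{error}$ on $(T-1, (T-1)(S-1))$ degrees of freedom.
Because cover data are typically non-normal and heteroscedastic, $F$ is
referred to a permutation null rather than the parametric distribution.
Year labels are reshuffled *within each site*, preserving the
repeated-measures blocking; a pooled (`global`) variant is available
behind a flag for designs where site identity is considered exchangeable
too. The within-site scheme is the default because it tests the year
effect conditional on persistent site differences, which is what the
blocking in a repeated-measures design is for. P-values use the
$(1 + \#\{F^\ast \ge F\})/(n_{reps} + 1)$ convention, which cannot return
zero from finite resampling. Post hoc year contrasts resample group
assignments *with replacement* from the two pooled year columns and are
reported as raw two-sided p-values (no multiplicity correction by
default, matching reporting at a fixed $\alpha$; a Holm flag exists on
the consistency test and `stats::p.adjust` can be applied to any table).

### Covariance-sign consistency across sites

For each unordered taxon pair, each site contributes the sign of the
pair's temporal covariance. A pair "occurs" at a site only when both taxa
have positive temporal variance there; an exactly zero covariance counts
toward occurrence but toward neither sign. Under a null of equal and
independent probability of either sign, the larger sign count $k$ out of
$n$ occupied sites is referred to an exact two-tailed binomial
probability, defined by probability ordering: all outcomes no more
probable than the observed one are summed (at $p = 0.5$ this equals the
doubled tail beyond $\max(k, n-k)$, capped at 1). "More extreme" is not
fully pinned down by verbal definitions of two-sided exact tests; the
probability-ordering convention was chosen because it is the standard
exact-test definition (it is what `binom.test` implements, which the test
suite uses as an independent cross-check).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `mean_cover_threshold` | 0.5 (%) | island-mean cover a taxon must exceed in ≥ 1 year to be focal |
| `min_sites` | 4 | minimum sites of presence for a focal taxon (capped at the design's site count) |
| phase windows | 2013–2017, 2018–2021 | a priori analysis windows; ≥ 3 years each, non-overlapping |
| `n_reps` | 10,000 | resampling replicates for all three procedures |
| `level` | 0.95 | central quantile-range mass for classification |

A phase needs at least three years because variances need two points and
a year-permutation null is degenerate below three. Percent scale
$[0, 100]$ is canonical; a flag accepts proportions on ingest. Sites are
weighted equally in the island mean, since plots are equal-area sampling
units. All variances and covariances use sample ($n-1$) normalization;
$\varphi$ is invariant to that choice when applied consistently, so it
only fixes the scale of reported covariances. Zero-variance taxa are
retained (contributing zero to numerator and denominator) so taxon sets
stay comparable across sites.

## The synthetic community generator

The generator emulates the statistical structure the analysis assumes,
not reef biology. True cover follows a lognormal fluctuation model,

$$
\log N_{s,t,i} = \log b_i + \lambda_i u_{s,t} + \varepsilon_{s,t,i},
$$

with per-taxon baselines $b_i$, a shared standard-normal site-year factor
$u$, and Gaussian residuals with standard deviation `sigma_log`.
Multiplicative lognormal noise is used because cover is positive and its
coefficient of variation is scale-free. Three modes set the covariance
structure: `independent` ($\lambda = 0$), `common_forcing`
($\lambda_i = \rho$ for all taxa), and `compensatory` (residuals drawn
jointly with constant negative pairwise correlation $\rho$, feasible only
for $\rho \ge -1/(k-1)$; infeasible values are a hard error). A
disturbance is modelled phenomenologically as per-taxon survival
multipliers applied cumulatively from a start year — the analysis only
consumes abundance trajectories, so no predator agent model is needed.
Totals are proportionally rescaled (with a message) only if they exceed
100%.

Observation noise is multinomial: each site-year draws `n_points = 2500`
point classifications (25 points/m² on a 10 m × 10 m plot) with
probabilities given by true cover plus an implicit remainder class. Point
placement is treated as exchangeable; spatial autocorrelation of real
stratified-random point sampling is deliberately not simulated. Defaults
(15 sites, 2013–2021, 12 taxa with baselines summing to 30% cover,
`sigma_log = 0.3`, decline from 2018 with per-year survival 0.72, so
cumulative ≈ 0.52 two years in) describe a fore-reef community that loses
roughly half its cover to a multi-year predator outbreak; they are loose,
scenario-level calibrations, not fits.

What passing tests on this generator do show: the estimators hit their
analytic limits, the nulls conserve what they must, classifications are
calibrated at the nominal rate under independence, and strong
compensatory or common-forcing structure is recovered with high power.
What they do not show: robustness to spatially autocorrelated point
sampling, observer misclassification, missing surveys, or non-lognormal
disturbance dynamics in real data.

## Numerical choices and degenerate inputs

- A community whose every taxon is temporally constant has an undefined
  index (denominator zero) and is a hard error; a zero numerator with a
  positive denominator returns exactly 0.
- Tiny negative numerator values (floating-point rounding of an exactly
  compensating community) are clamped to 0, and the index is capped at 1.
- An all-constant ANOVA input yields an undefined $F$ (reported `NA`) and
  $p = 1$ by convention.
- Duplicate `(site, year, taxon)` records are a hard ingest error naming
  the offending key; missing combinations are zero-filled with a warning,
  because absence from a year's point sample is a true zero under
  point-intercept sampling.
- In the `compensatory` mode at the feasibility boundary the residual
  covariance matrix is singular; draws use an eigendecomposition-based
  multivariate normal sampler (`MASS::mvrnorm`) with a loose
  positive-semidefiniteness tolerance.
- Exact `phi = 0` on two-taxon compensated communities is a property of
  constructed (arithmetic-scale) matrices; under the lognormal generator
  with $\rho = -1$ the index approaches 0 only in the small-noise limit,
  $\varphi \approx (e^{\sigma^2}-1)/(2e^{\sigma^2})$, because
  $e^{\varepsilon} + e^{-\varepsilon}$ is not constant.

## Problem sizes used by the test suite

Calibration and power checks run at reduced but statistically meaningful
sizes chosen once: 500 simulated site-phases with 500-replicate nulls for
the 95% coverage check (asserted within two Monte-Carlo standard errors),
500 exchangeable-null datasets for the type-I error and p-value-uniformity
checks of the permutation ANOVA, 100 site-phases per mode for the power
checks (power > 80% required for two-taxon full compensation at
`sigma_log = 0.1` and full common forcing at `sigma_log = 0.3`), and
10,000 replicates for the bit-exact variance-conservation check on a
12-taxon × 5-year matrix.

## Known limitations

The pipeline requires balanced designs (every site surveyed every year in
a phase) for the ANOVA stage; the synchrony and consistency stages only
need each site's own years. Alternative synchrony metrics, detrending,
mixed-effects models, and spatial metapopulation partitioning of
synchrony are out of scope. Taxon life-history labels are carried as
pass-through metadata and never enter any computation.
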