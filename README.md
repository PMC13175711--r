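# reefsync

Population synchrony and portfolio-effect analysis for benthic
percent-cover monitoring data.

Long-term reef monitoring programs estimate the abundance of coral taxa as
percent cover in fixed plots, year after year. A recurring question is
whether total community cover is stabilized by *asynchrony* among its
member populations — the ecological analogue of a diversified investment
portfolio — or destabilized when a shared disturbance (bleaching, predator
outbreak) drives all populations down together. `reefsync` provides a
tested, reusable pipeline for answering that question from a long-format
`site, year, taxon, cover` table.

## The statistic at the core

For one site (or the island mean), with `v` the temporal covariance matrix
of the taxa across years, the community synchrony index is

    phi = ( sum_ij v_ij ) / ( sum_i sqrt(v_ii) )^2

The numerator equals the temporal variance of total community cover, so
`phi = 1` when populations fluctuate perfectly synchronously and `phi = 0`
when the community total never fluctuates (perfect compensation).

Around this index the package implements:

- **Variance-preserving permutation nulls** — each taxon's values are
  independently shuffled across years (preserving every population's
  variance exactly) and `phi` recomputed, 10,000 times by default.
  Observed values outside the central 95% quantile range of the null are
  significant evidence of negative or positive covariation among
  populations.
- **Bootstrapped repeated-measures ANOVA** — a within-subjects F-ratio for
  year effects on total cover, referred to a permutation null built by
  reshuffling year labels within sites (the parametric F distribution is
  avoided because cover data are typically non-normal and
  heteroscedastic), plus bootstrap post hoc year contrasts.
- **Covariance-sign consistency tests** — for each taxon pair, an exact
  two-tailed binomial test of whether the sign of temporal covariance is
  consistent across sites more often than a fair coin would produce.
- **A synthetic community generator** — lognormal cover fluctuations with
  independent, common-forcing, or compensatory structure, an optional
  phase-2 systematic decline, and multinomial point-intercept observation
  noise (2,500 points per 10 m × 10 m plot), so the full pipeline is
  testable end to end without field data.

## Worked example

Simulate the default 15-site, 2013–2021, 12-taxon design — independent
lognormal population dynamics with a systematic decline (per-year survival
0.72) starting in 2018 — and run the full analysis in two a priori phases
(2013–2017, 2018–2021):

```r
library(reefsync)
report <- run_analysis(list(seed = 3, n_reps = 1000))
print(report)
#> <analysis_report>
#>   focal taxa: 12 (group_01, group_02, group_03, ...)
#>   phase1: site SI 0.02-0.32, island-mean SI 0.07 (not_significant); 0/15 sites + covar
#>   phase2: site SI 0.56-0.87, island-mean SI 0.97 (positive_covariation); 15/15 sites + covar
```

In phase 1 every site's synchrony index sits inside its permutation null's
95% quantile range: populations fluctuate, but no more synchronously than
randomly co-fluctuating populations with the same individual variances —
the portfolio-effect regime. In phase 2 the shared decline drives the
index far above the null at every site:

```r
report$synchrony_table[17:20, c("site", "observed_si",
                                "null_quantile_low", "null_quantile_high",
                                "classification")]
#>       site observed_si null_quantile_low null_quantile_high       classification
#> 17 site_01       0.603            0.0205              0.445 positive_covariation
#> 18 site_02       0.764            0.0296              0.454 positive_covariation
#> 19 site_03       0.812            0.0135              0.360 positive_covariation
#> 20 site_04       0.658            0.0127              0.365 positive_covariation

report$anova
#>    phase f_observed df_between df_error   p_boot n_reps
#> 1 phase1      0.586          4       56 0.663337   1000
#> 2 phase2    292.151          3       42 0.000999   1000
```

Total cover shows no year effect in phase 1 (F on 4 and 56 df, permutation
p = 0.66) and a massive one in phase 2. Covariance signs tell the same
story: 2 of 66 taxon pairs are consistently signed across sites in phase 1
versus 61 of 66 in phase 2 (`report$pair_consistency`). Write all report
tables as CSVs with `write_report(report, "out/")`.

A thin command-line front end ships in `inst/scripts/reefsync`
(`simulate`, `analyze`, `report`, `selftest` subcommands).

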