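# rwdemog

Stage-structured demography and calving trends of right whales.

North Atlantic right whales (*Eubalaena glacialis*, NARW) number only a
few hundred animals and have been declining since 2010, while the three
main Southern right whale (*E. australis*) populations are recovering
strongly. `rwdemog` implements the two analyses behind that comparison,
for population ecologists and conservation scientists:

1. **A three-stage female projection-matrix model.** Stages calf /
   immature / adult, with retention and advancement probabilities derived
   from annual survival `σ` and stage duration `d` by the
   fixed-stage-duration equations `P = σ(1−σ^(d−1))/(1−σ^d)`,
   `G = σ^d(1−σ)/(1−σ^d)` (so `P + G = σ`), and adult fecundity
   `f = female_fraction / calving_interval`. The package computes the
   dominant eigenvalue `λ`, stable stage distribution `w`, reproductive
   values `v`, sensitivities `s_ij = v_i w_j` and elasticities
   `e_ij = (a_ij/λ) v_i w_j`, and runs seeded, demographically stochastic
   multi-year projections (trinomial stage fates, binomial births) with
   ensemble quantile summaries.
2. **A negative-binomial calf-count trend comparison.** Annual calf
   counts from four calving grounds (NARW, southwest Australia, South
   Africa, eastern South America) are fit with an NB2 log-link GLM,
   `log μ_st = a_s + b_s·year`, giving per-population annual growth rates
   `100·b_s` %/year and Wald chi-square pairwise slope contrasts with
   Benjamini–Hochberg FDR adjustment.

A synthetic-data module generates NB2 calf-count panels with known
ground truth (matching the real panel's unbalanced 1992–2016 design), so
the whole pipeline is testable without any external download.

## Worked example

```r
library(rwdemog)

vr <- vital_rates()            # best observed NARW female survival rates
A  <- build_matrix(vr)
round(A, 5)
#>             calf immature  adult
#> calf     0.00000  0.00000 0.1250
#> immature 0.96299  0.86368 0.0000
#> adult    0.00000  0.11139 0.9664

an <- analyze(A)
an
#> Asymptotic analysis: lambda = 1.03968 (3.97% per year)
#> Stable stage distribution:
#>     calf immature    adult
#>  0.06762  0.36998  0.56240
#> ...
#> Elasticities (sum to 1):
#>            calf immature   adult
#> calf     0.0000  0.00000 0.04740
#> immature 0.0474  0.23263 0.00000
#> adult    0.0000  0.04740 0.62516
```

`λ ≈ 1.040`: with the best observed survival and a four-year calving
interval the population could grow 4%/year. Adult survival carries ~63%
of the elasticity — adult female mortality dominates the growth rate.

```r
v0 <- initial_vector_from_ssd(123, an)   # 123 females in 1990
v0
#>     calf immature    adult
#>        8       46       69

ens <- project_stochastic(vr, v0, years = 25, reps = 1000,
                          seed = 1, start_year = 1990)
ens
#> Stochastic projection ensemble: 1000 replicates x 25 years (seed 1)
#>   final-year total females: median 324 (2.5%-97.5%: 266-393)
```

Had survival stayed at its best observed level, the median 2015 female
population would have been ~324 — about twice what was actually
observed, so the shortfall is anthropogenic rather than intrinsic.

```r
d   <- generate_counts(trend_scenario(), seed = 3)  # synthetic panel
fit <- fit_nb_glm(d)
site_growth_rates(fit)[, c("site", "pct_per_year", "pct_se")]
#>    site pct_per_year    pct_se
#>    NARW     2.522587 0.9836979
#>   SRWOz     6.583255 0.8144663
#>  SRWSAf     6.429838 0.8834203
#>  SRWSAm     5.471399 0.7346088
pairwise_slope_contrasts(fit)[1, ]
#>  site1 site2  difference df    chisq     p_value  p_adjusted
#>   NARW SRWOz -0.04060668  1 10.10966 0.001474943 0.008849660

extrapolate_abundance(270, 0.0198, 26, round_result = TRUE)
#> [1] 450
```

The NARW slope is roughly a third of the Southern right whale slopes, and
the difference survives FDR adjustment. The final line is the geometric
cross-check linking the 1.98%/year calving index to an independent
26-year abundance series.

`run_paper_analysis()` chains all of the above from one YAML config
(`inst/extdata/default_config.yaml`) and writes matrix, analysis report,
trajectories, ensemble summary and trend tables, each stamped with the
seed and a config hash. A thin command-line front end with
`build-matrix` / `analyze` / `project` / `trend` / `simulate` /
`run-paper` subcommands lives in `inst/scripts/rwdemog.R`.

## Documentation

The methods vignette (`vignettes/right-whale-demography.Rmd`) describes
the model, its assumptions, parameter defaults and their provenance, the
stochastic engine and its birth-timing convention, the trend model, what
the synthetic generator does and does not emulate, and known limitations.
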