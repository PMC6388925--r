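# posdev

Positive-deviance analysis for multi-objective agricultural household
surveys.

Development programmes must weigh several objectives at once — food
security, nutrition, income, environmental sustainability, gender equity —
and trade-offs between them defeat one-size-fits-all recommendations.
`posdev` identifies **positive deviants**: households whose outcomes are
better than expected *given their resource endowments*, simultaneously
across all five dimensions. Their uncommon practices, observed in
follow-up visits, become locally proven, resource-matched intervention
options for similar households. The intended users are researchers and
development practitioners working with RHoMIS-style multi-indicator
household surveys.

## Method at a glance

For each household *i* and each performance dimension *d*:

1. **Indicator** `y_id`: caloric food security (PC-1 of the standardised
   sufficiency ratio min(availability/2550, 1) and food-secure months
   12 − m), dietary diversity (harmonic mean of seasonal HDDS), cash
   income (farm + off-farm), GHG score (−1 × emissions), and gender
   equity (1 − w·2·|f − ½|), each outlier-capped.
2. **Relative performance**: the residual `e_id = y_id − x_iᵀβ̂_d` of a
   median regression (τ = 0.5, check loss ρ₀.₅(e) = ½|e|) on land,
   livestock, household size (MAE), region and village market access,
   with covariates chosen per dimension by AIC
   (2k + 2n·log(mean check loss)) over all 2⁵ subsets.
3. **Pareto ranking**: household *a* dominates *b* iff `e_a ≥ e_b` in
   every dimension with one strict inequality; positive deviants are the
   rank-1 front plus the rank-2 front (non-dominated after removing
   rank 1).
4. **Profiling**: mean deviance of deviants by 10 land deciles × a
   livestock median split (20 resource strata), z-scaled over all
   households; correlations between deviance dimensions.
5. **Case selection**: one deviant per non-empty stratum, rank-1
   preferred, maximising mean crowding distance over four household
   characteristics (greedy + swap local search, oracle-verified optimal
   on small instances).
6. **Resource homologues**: every household matched to its k = 3 nearest
   visited deviants by Euclidean distance in standardised six-resource
   space; its practice menu is the union of their observed practices.

A seeded synthetic-survey generator with planted deviants (known ground
truth) makes every stage testable end to end.

## Worked example

```r
library(posdev)

# a synthetic survey at study scale: 521 households, 44 villages, 3 regions
gen     <- generate_households(synthetic_spec(n_households = 521, seed = 42))
catalog <- generate_practice_catalog(gen$truth, seed = 42)

run <- run_positive_deviance(gen$records, pd_config(), catalog = catalog)
print(run)
#> <pd_run> positive-deviance pipeline
#>   households analysed: 521 (0 dropped)
#>   positive deviants: 49 (rank 1: 15, rank 2: 34)
#>   food-security PC-1 variance: 66%
#>   strata with deviants: 18 of 20 occupied
#>   homologue stage: run (14 practices targeted)
```

About 10% of households are positive deviants — on or immediately behind
the non-dominated front of the residual space — and 18 of the 20 resource
strata contain at least one, so success cases exist across nearly the full
endowment range. The selected per-dimension performance models:

```r
print(run$residuals)
#> <pd_residuals> 521 households x 5 dimensions
#>   food_security      ~ land_ha+livestock_tlu+market_access (AIC -847.0)
#>   dietary_diversity  ~ land_ha+livestock_tlu+market_access (AIC -263.2)
#>   cash_income        ~ land_ha+market_access (AIC 6808.7)
#>   ghg_score          ~ land_ha+livestock_tlu+market_access (AIC 3759.3)
#>   gender_equity      ~ livestock_tlu+region+market_access (AIC -2653.6)
```

Each residual is the household's performance relative to what its
endowments predict; AIC picked a different covariate subset per dimension.
Practice targeting counts how many households have each practice in their
homologue-derived menu:

```r
head(run$practice_targeting[order(-run$practice_targeting$n_target_households), ], 4)
#>    practice_code n_target_households     share
#> 2            P02                 247 0.4740883
#> 3            P03                 208 0.3992322
#> 13           P13                 188 0.3608445
#> 1            P01                 170 0.3262956
```

Real surveys enter through `read_household_table()` (CSV or XLSX, with a
configurable column map) and `validate_households()`; a YAML config read
by `load_config()` controls every tunable (capping percentile,
gender-equity weights, candidate covariates, front depth, homologue k).
A thin command-line wrapper is included:

```sh
Rscript inst/cli/posdev.R synth --outdir demo --seed 5
Rscript inst/cli/posdev.R run --input demo/survey.csv \
    --catalog demo/practices.csv --outdir results
```

## Package layout

- `R/` — implementation (indicators, median-regression residuals, Pareto
  ranking, deviance profiling, case selection, homologues, synthetic
  generator, pipeline, I/O and config)
- `tests/testthat/` — unit, property and acceptance tests with
  independent brute-force oracles
- `vignettes/positive-deviance-methods.Rmd` — the model, its assumptions,
  numerical choices and limitations
- `inst/cli/posdev.R` — command-line entry point
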