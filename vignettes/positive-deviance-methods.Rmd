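---
title: "Identifying positive deviants in multi-objective household surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying positive deviants in multi-objective household surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posdev)
```

## The problem and the approach

Agricultural development pursues several objectives at once — food
security, nutrition, income, environmental sustainability, social equity —
and trade-offs between them mean no single "best practice" exists for all
households. The positive-deviance approach turns this around: instead of
modelling what *should* work, it looks for households that already achieve
unexpectedly strong outcomes across all objectives *given their resources*,
and treats their uncommon practices as locally proven candidate
interventions for households with similar resource endowments.

`posdev` implements the quantitative backbone of that approach for
RHoMIS-style multi-indicator household surveys (one row per household:
household size in male adult equivalents, land and livestock holdings,
market orientation, food availability, dietary diversity scores, incomes,
greenhouse-gas totals, decision-making shares). The pipeline has six
stages:

1. **Performance indicators** — five scores per household.
2. **Relative performance** — median-regression residuals per dimension.
3. **Pareto ranking** — rank-1 and rank-2 non-dominated households are the
   positive deviants.
4. **Deviance profiling** — where deviance concentrates across resource
   strata, and how its dimensions correlate.
5. **Case selection** — a maximally diverse deviant per stratum for
   qualitative follow-up.
6. **Resource homologues** — every household matched to its most similar
   visited deviants, yielding a household-specific practice menu.

## The five performance indicators

| Dimension | Indicator | Construction |
|---|---|---|
| Food security | caloric food security | PC-1 of standardised sufficiency ratio and food-secure months |
| Nutrition | dietary diversity | harmonic mean of good- and lean-season HDDS |
| Income | cash income | farm-gate sales + off-farm income (US$/yr) |
| Sustainability | GHG score | −1 × total emissions (kg CO₂-eq/yr) |
| Social equity | gender equity | 1 − w(type) · 2·\|female share − 0.5\| |

**Caloric food security.** The sufficiency ratio divides food availability
(already a per-MAE, per-day quantity) by the recommended daily intake
(default 2550 kcal/MAE/day, Tanzania's official recommendation) and caps at
100%: beyond full sufficiency, extra calories do not add security.
Consistency is the count of food-secure months, `12 − insecure months`.
Because the two measures have incommensurable units, both are standardised
before the principal-component decomposition, and the household scores on
the first component — sign-oriented to correlate positively with both
inputs — form the composite. The fraction of variance PC-1 explains is
reported with every fit.

**Dietary diversity.** The harmonic mean of the two seasonal HDDS values
penalises a poor lean season more than the arithmetic mean would; a diverse
good season cannot fully compensate a monotonous lean one. At an HDDS of 0
in either season the harmonic mean is undefined; we define the indicator as
0 there, its limiting infimum.

**Gender equity.** Equal decision-making (female share 0.5) scores 1;
deviations are discounted linearly at a household-type-specific weight
(default 1.0 for couple-type households, 0.5 for single-headed ones, where
a skewed share is partly structural). The exact published per-type formulae
are not reproducible from the main text of the underlying survey
methodology, so this family is a documented, configurable stand-in with the
same structure: optimum at 0.5, type-specific discounting.

**Outlier capping.** Each indicator is capped by replacing values above a
validity bound (default: the empirical 99th percentile; absolute bounds
configurable per indicator) with the maximum observed in-range value. The
operation is idempotent and never invents values. Low-end capping is
available but off by default, since implausible survey values are
overwhelmingly right-tail artefacts.

## Relative performance

Positive deviance is *performing better than expected*, not performing
best. For each indicator independently we fit a median regression (quantile
regression at τ = 0.5, minimising the check loss ρ₀.₅(e) = 0.5·|e|) on
household endowments — land, livestock, household size, region, and market
access — and use the residual, observed minus expected performance, as the
household's relative performance. Market access is proxied by the village
mean of market orientation, evening out household-level utilisation
differences.

Covariates are selected per dimension by exhaustive search over all 2⁵
subsets of the five candidate groups (region's dummy columns enter and
leave together). Because no standard AIC exists for quantile regression, we
use the asymmetric-Laplace profile form with constants dropped,

AIC = 2k + 2n·log(mean check loss),

which is a monotone function of the fit's mean check loss penalised by the
parameter count — the common practice for τ-fixed model screening. Exact
AIC ties break toward fewer covariate groups, then earlier candidate order;
both the AIC variant and the exhaustive search are deliberate,
documented choices where the method description leaves the details open.

Numerical notes: fits use the Barrodale–Roberts simplex (an exact vertex
solution); when the outcome admits an exact linear fit the interpolating
solution is taken directly from the QR factorisation (it is trivially
check-loss optimal, and fully degenerate problems can stall a simplex), and
its AIC is reported as −∞ with a warning. Rank-deficient candidate subsets
are skipped during the search; model selection fails only if every subset
is unfittable. Solution non-uniqueness — routine with discrete outcomes —
is accepted: any check-loss optimum is valid.

## Pareto ranking

In the 5-dimensional residual space, household *a* dominates *b* when *a*
is at least as good everywhere and strictly better somewhere. Rank 1 is the
non-dominated front; removing it and recomputing gives rank 2, whose
members are dominated only by rank-1 households. Positive deviants are the
union (default `max_front_rank = 2`, configurable). Comparisons are exact
on floating-point residuals — no epsilon — because residuals are
continuous and exact ties are structural (duplicate records), handled by
co-ranking. The implementation is a simple O(n²d) pairwise peel, verified
in the test suite against an independently written brute-force oracle; at
survey scale (n ≈ 500) it runs in milliseconds.

## Deviance profiling

Residuals are z-scaled per dimension over **all** households (sample
standard deviation), so subgroup means read as standard deviations from the
population mean; the same convention is used by the correlation analysis
downstream. Households are stratified by land-endowment deciles (rank
based; tied values share the lower decile) crossed with a median split of
livestock holdings — with the typical livestock median of 0, the split
reads as absence/presence. The profile tables report deviants' mean
residuals per paired land strata (1+2, …, 9+10, household-weighted),
per livestock class, and overall (raw and z-scaled), plus Pearson
correlations between deviance dimensions over deviants (unadjusted p <
.05 flags) and a deviant-versus-others comparison table. For the
comparison's numeric characteristics the default is Welch's t-test rather
than Student's — robust to unequal group variances at negligible cost —
with `group_test = "student"` available for exact replication of the
classical convention.

## Diverse case selection

One deviant per non-empty stratum is selected for follow-up, maximising
the mean crowding distance of the selected set over household size, land,
livestock and market access (min–max normalised within the deviant pool;
region is excluded as categorical). Within a stratum, rank-1 deviants are
always preferred over rank-2, regardless of diversity. The classical
crowding distance assigns the boundary points infinity, which makes a mean
objective ill-defined; we use a finite boundary contribution of 2 per
characteristic, strictly above the interior maximum of 1, preserving
"extremes are most diverse" while keeping the mean usable. The "stepwise
procedure" is implemented as a deterministic greedy pass over strata
(ascending land decile, low livestock first) followed by single-swap
improvement passes until no swap raises the objective; on all instances
small enough for exhaustive enumeration the result attains the optimum
(tested on 81 seeded instances). Whether distances are computed within the
provisional selection (default) or the full deviant pool is a config
switch, as the original procedure is ambiguous on this point.

## Resource homologues and practice menus

Each household is matched to its `k = 3` nearest visited deviants by
Euclidean distance in a six-resource space: agro-ecological ability,
labour, financial capital, land, livestock, social capital. The published
proxy formulae for these axes live in supplementary material that is not
part of the main text, so the axes are configurable expressions with
documented defaults (crop diversity, MAE, total income, land ha, TLU,
village market access). Profiles are standardised before distances —
otherwise income's scale would dominate the metric — and Euclidean (not
Mahalanobis) distance is kept deliberately: surpluses and shortfalls in a
resource are treated symmetrically, reflecting partial convertibility
between resources. A deviant target matches itself at distance 0 by
default (so homologue counts over all households sum to the full sample);
ties break by ascending household id. A household's practice menu is the
union of practices observed with its homologues; per-practice target
counts are the number of households whose menu holds the practice.

## The synthetic-data generator

Because the original survey data cannot ship with the package, every stage
is validated against a seeded generator that emulates the *structure* of
the study conditions, not Tanzanian marginals: 521 households by default,
spread ~12 per village over 44 villages in 3 regions (20/20/4); log-normal
land (mean ≈ 4 ha); zero-inflated log-normal livestock (≈55% zeros, so the
median split degenerates to absence/presence as in the field data);
truncated-normal household size (mean 4.25 MAE); village-level beta market
orientation; binomial HDDS; incomes log-normal in land and market access;
GHG linear in livestock and land.

Every outcome is driven by the endowment covariates plus noise, so the
median regressions have real structure to remove. On top sits a continuous
latent "management quality" (sd 0.6 in per-outcome noise-sd units — the
one-time realism choice for within-stratum behavioural variation), and a
planted 10% of households receive a favourable quality shift of
`deviant_effect` (default 2). Quality coefficients are set to exactly one
noise-sd per outcome, so `deviant_effect` reads directly as the planted
shift in noise-sd units; outcome bases are placed so truncation at
indicator bounds (the sufficiency cap, the 0–12 month range, the GHG
floor) stays rare and does not eat the planted signal. For gender equity
the quality pulls the decision share multiplicatively toward parity.

What passing recovery tests show — and what they do not: with a 2-sd
planted effect at n = 500, the pipeline recovers planted deviants within
the rank-≤2 fronts at mean recall ≈ 0.73 and tracks latent quality with
mean rank correlation ≈ 0.83 over 10 seeds, and with zero effect recall
falls to the front-share baseline. This validates the machinery —
residualisation removes endowment effects, fronts enrich for genuine
behavioural quality — under an additive, all-dimension signal. Real
deviance need not be additive or all-dimensional; specialists, reporting
error and unmodelled context will lower real-world recall in ways the
generator does not emulate.

Problem sizes in the shipped tests (oracle checks at n ≤ 200, recovery at
n = 500 × 10 seeds, study-scale runs at n = 521) were chosen so the full
suite validates every contract at survey scale while running in well under
a minute.

## Known limitations

- The gender-equity family and the six resource proxies are structural
  stand-ins for unpublished supplementary formulae; replicating a specific
  study requires configuring them.
- The AIC variant for median regression is a pragmatic convention; ranking
  of models can differ under other quantile-regression information
  criteria.
- Front membership is sensitive to indicator definitions; adding or
  redefining a dimension changes the deviant set.
- No multiple-testing correction is applied to the profiling tables'
  p-values (they are descriptive flags, mirroring the reporting
  convention), and no inference is attached to regression coefficients —
  the method uses only residuals.
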