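---
title: "Methods: multi-environment trial biometry with metbiom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment trial biometry with metbiom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metbiom)
```

## The problem

Crop improvement programs evaluate a panel of genotypes across several
seasons or locations in replicated field trials, here a balanced
randomized complete block design (RCBD): `G` genotypes x `Y` years x `R`
replicate blocks, each plot scored for `T` traits. The questions such a
trial answers are always the same four: how much of the observed
variation is heritable (variance components, heritability, genetic
advance); how traits move together at the genetic versus phenotypic
level (correlations from mean cross-products); which traits drive the
economic trait (regression); and which genotypes are both good and
stable across years (divergence grouping and adaptability ranking).
`metbiom` implements that full chain on one long-format plot table.

## Model and estimators

For one trait, the combined multi-year decomposition is

$$y_{ijk} = \mu + g_i + y_j + (gy)_{ij} + r_{k(j)} + \varepsilon_{ijk},$$

with genotype effects shared across years; all year-specific genotype
deviation sits in the interaction term. Within a single year the
analysis reduces to the two-way RCBD with sources replication
(`R - 1`), genotype (`G - 1`) and error (`(G - 1)(R - 1)`).

Variance components are classical moment (expected-mean-square)
estimators, not REML — deliberately, because this is the estimator
lineage of the standard genetic-parameter tables this package
reproduces:

* `sigma2_e = MS_error`
* `sigma2_g = (MS_genotype - MS_error) / r`, truncated at 0 with a flag
  when the moment estimate is negative (keeps heritability in `[0, 1]`)
* `sigma2_p = sigma2_g + sigma2_e`

Derived parameters: coefficients of variation
`GCV, PCV, ECV = 100 * sqrt(sigma2) / mean` (so `PCV^2 = GCV^2 + ECV^2`
is an exact identity and a standing test assertion); broad-sense
heritability `h2b = sigma2_g / sigma2_p`, classified low/moderate/high
at 30% and 60%; genetic advance `GA = k * h2b * sqrt(sigma2_p)` and gain
`GG = 100 * GA / mean`. The selection differential defaults to
`k = 2.06` (5% selection intensity). The source tables this package
validates against never state `k`; 2.06 is the standard constant and is
confirmed numerically — it reproduces the published genetic-advance
column (e.g. 439.95 g/plant for yield per plant) to print precision.

Precision statistics follow the same error line: `SE = sqrt(sigma2_e/r)`,
`CV% = 100 sqrt(sigma2_e)/mean`, and the critical difference
`CD(alpha) = t_{1-alpha/2, df_e} sqrt(2 sigma2_e / r)`, i.e. the least
significant difference between two genotype means (two-sided t quantile,
so CD(5%) uses the 97.5th percentile).

### Combined genotype-by-year ANOVA

Replication is nested within year: `df_rep = Y(R - 1)`. The published
combined table this mirrors prints a replication df of 1, which
contradicts its own residual df (156 = 317 - 3 - 52 - 2 - 104); the
df-consistent nested layout is implemented and the printed df treated
as a typographical artifact. Genotype, year and interaction are tested
against the residual MS by default; the random-year convention (genotype
against the interaction MS) is available via
`genotype_denominator = "interaction"`. A `% total SS` column supports
the conventional partition narrative.

### Correlations

For a trait pair the analysis of covariance mirrors the ANOVA: error
covariance is the error mean cross-product, genotypic covariance is
`(MCP_genotype - MCP_error) / r`, phenotypic covariance their sum.
Then `r_g = cov_g / sqrt(sigma2_g_x sigma2_g_y)` and analogously `r_p`.
Three deliberate conventions:

* `|r_g| > 1` happens legitimately with moment estimators; such values
  are capped at 0.99 and flagged, matching the behaviour visible in
  standard MET software output (runs of printed 0.99 values are the
  signature of that cap).
* `r_g` is reported only when both genotypic variance estimates are
  positive; otherwise it is flagged not-estimable, the most plausible
  mechanism behind dashes in published genotypic-correlation tables.
* Pooled-over-years components use genotype mean cross-products across
  the full table (effective replication `Y * R`) against the
  combined-model residual. A share (`1/Y`) of the interaction
  cross-products then travels with the genotypic component; this is the
  standard behaviour of pooled mean-cross-product estimators and is
  asserted quantitatively in the test suite rather than hidden.

Significance for both correlations uses `t = r sqrt(df/(1 - r^2))` with
`df = G - 2`, the genotype-mean basis consistent with a 53-genotype
panel.

### Yield regression

Ordinary least squares of fresh yield on the component traits, fitted on
replicate-averaged genotype means per year (`n = G`); plot-level fitting
is available behind a flag. Yield-per-plant is near-definitional for
fresh yield, and including it (as the source tables do) is structurally
collinear; the fit warns but proceeds, fidelity first. Contribution
profiles are sequential (type-I) shares in the stated predictor order,
normalized so shares sum exactly to the model R²; standardized
coefficients are attached as the order-free view.

### Divergence grouping

Mahalanobis `D2(i,j) = (x_i - x_j)' S^{-1} (x_i - x_j)` over genotype
trait-mean vectors, with `S` the pooled within-genotype covariance of
replicate-level residuals. `D2` is invariant to nonsingular linear
transformations of the trait space (a property test). When `S` is
singular a Moore-Penrose pseudo-inverse is available behind an explicit
flag; when replicate-level data are absent entirely, a standardized
Euclidean fallback is provided with a logged method downgrade.

Grouping offers Tocher's method (threshold = the largest row-wise
nearest-neighbour distance; admit while the average within-cluster
distance stays at or below it; ties broken by input order, so the result
is deterministic) and hierarchical Ward/average linkage cut to `k`.
Summary tables report intra/inter-cluster mean distances; because
published divergence summaries print magnitudes consistent with `D`
(not `D2`) on standardized multi-trait data, `cluster_summary()` has a
`scale = "sqrt"` switch, used by the pipeline's report output. The
underlying publication does not state which grouping route or
standardization it used, so cluster memberships and distances are shape
targets only, never value targets.

### Geometric Adaptability Index

`GAI` per genotype and trait is the geometric mean of the genotype's
year means. By AM-GM it is at most the arithmetic mean, with equality
only under identical year performance — the index rewards level and
consistency simultaneously. Ranking is descending in GAI (rank 1 =
highest) for every trait, including plant height: the source table
ranks its tallest-GAI genotype first on plant height, so no trait is
treated as lower-is-better. Ties take average ranks (rank columns sum
to `G(G+1)/2`, a standing assertion). Mean rank (MR) averages a
genotype's ranks over traits; R.MR re-ranks unrounded MR ascending;
occurrence counts ranks at or under 10. Selection takes genotypes with
at least 5 top-10 occurrences, with an optional auxiliary admission by
a trait's own rank column (the published "superior group" includes one
genotype admissible only by its yield ranking, so the union rule is
configurable; neither published list is an acceptance target).

## The synthetic trial generator

Real plot data for the motivating study are not deposited, so every
estimator is validated against `simulate_met()`, which draws from the
model above: genotype effect vectors jointly multivariate normal across
traits (inducing recoverable genotypic correlations), errors jointly
normal under a separate (default identity) correlation, year and
interaction effects independent per trait, optional block variance
(default 0 — published block sums of squares in such trials are
negligible). The truth ledger is computed analytically from the
configuration, never from the realized sample.

`table1_like_config()` packages the reference trial's first season:
per-trait grand means, `sigma2_g` and `sigma2_e` copied from the
published table (heritabilities 0.58–0.99, GCVs ~6–90% across seasons),
exchangeable genetic correlation 0.4. The published work never states
its year or interaction variances per trait; the defaults
`sigma2_gy = 1.92 sigma2_g` and `sigma2_y = 1.51 sigma2_g` are
calibrated once so that, for the yield trait, the expected combined-ANOVA
partition reproduces the published ~41/26/32% genotype/year/interaction
split. This is a calibration choice, recorded here, not a published
value.

What the generator does *not* emulate: the right skew and strict
positivity of real yield data. With genotypic CVs up to 90%, a Gaussian
model necessarily produces occasional negative plots and even negative
year means. The generator therefore carries an explicit positivity
switch (`positivity = "truncate"`, flooring at 1% of the grand mean
*after* effect summation, with a truncation count in the ledger). It is
off by default because truncation distorts variances; analyses that
require positivity (CV, GAI) on the full-scale fixture enable it
deliberately. A green fixture test therefore establishes correct
estimator algebra and calibrated sampling behaviour under Gaussian
effects — not distributional realism of crop yields.

## Numerical and validation choices

* Reference-table identity checks: the published genetic-parameter table
  prints inputs (mean, `sigma2_e`, `sigma2_g`) and derived columns to
  2 decimals. Recomputing derived cells from the *rounded* inputs cannot
  generally hit half of the last printed digit — for the smallest
  variance entries (e.g. `sigma2_e = 0.02`) input rounding alone is 25%
  relative error. The acceptance test therefore asserts every derived
  cell within half a printed digit **plus first-order propagated input
  rounding**, and additionally asserts the well-conditioned marquee
  cells at plain print precision. All 132 derived cells of the first
  season pass the propagated bound.
* The published combined-ANOVA percent column is mutually inconsistent
  with its own SS column at the last digit (the percentages imply a
  total SS of ~28615, the SS sum to 28603); the identity check allows
  0.03 percentage points for exactly that discrepancy.
* The published occurrence column disagrees with its own rank rows for
  two adjacent genotypes (an apparent swap); the acceptance test asserts
  the 51 consistent rows match and that exactly those two differ in the
  documented direction.
* Monte-Carlo recovery tests compare mean estimates against truth within
  3 Monte-Carlo standard errors at reduced replicate counts (60–200
  replicate simulations) to keep the default suite under a minute for
  the statistical tests; the null size of the genotype F-test is checked
  on 2000 small trials.
* All percentages and ranks are carried at full precision internally;
  rounding happens only in the pipeline's `"report"` mode (2 decimals).
* Config files are JSON rather than YAML, keeping the dependency
  footprint to `jsonlite`.

## Known limitations

* Balanced designs only: missing plots are a hard error by design, and
  no imputation is offered — unbalanced expected-mean-square algebra is
  out of scope.
* Moment estimation only; no REML, no narrow-sense heritability, no
  AMMI/GGE-type stability statistics beyond the GAI.
* Gaussian effects only in the simulator; no overdispersed or skewed
  error families.
* Published correlation, regression-R² and cluster values depend on the
  undeposited raw plot data and are deliberately not reproduction
  targets; the package validates those stages by simulation recovery
  and brute-force oracles instead.
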