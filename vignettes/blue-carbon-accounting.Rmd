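---
title: "Blue carbon emissions accounting: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blue carbon emissions accounting: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bluecarbon)
```

## The accounting model

Tidal marshes, mangroves, and seagrass meadows sit on organic-rich
sediments that hold large stocks of previously sequestered carbon ("blue
carbon"). When these ecosystems are converted — drained for agriculture,
excavated for aquaculture, degraded by eutrophication — part of the carbon
in the vegetation and the top meter of sediment is oxidized and reaches
the atmosphere. The annual emission from each ecosystem type is modelled
as a product of three factors:

$$ E = A \times 10^6 \;\cdot\; \frac{r}{100} \;\cdot\; D \times 10^{-9}
\quad \text{[Pg CO}_2\ \text{yr}^{-1}\text{]} $$

where $A$ is global extent (Mha), $r$ the annual conversion rate (% of
extent per year), and $D$ the susceptible carbon density (Mg CO$_2$/ha).
$D$ itself is the near-surface carbon stock (biomass plus top meter of
sediment, converted from Mg C/ha with the molar-mass ratio $44/12 \approx
3.67$) scaled by the fraction of that stock assumed emitted upon
conversion — bounded between 25% and 100%, with the midpoint 62.5% as the
central estimate.

Each factor is known only as a published range with a central estimate,
so the package propagates all three through a Monte Carlo simulation
(50,000 iterations per ecosystem by default) and reports the median and
the nonparametric 90% confidence interval (empirical 5th and 95th
percentiles) of the emissions draws.

## Calibrating distributions from ranges

A published `(min, central, max)` carries no distributional information,
so a convention is required.

* **Truncated normal (default).** The range is read as a $\pm 2\sigma$
  interval: mean at the central estimate, $\sigma = (\max - \min)/4$,
  truncated to $[\min, \max]$. The mean stays at the central estimate
  even when it is not the midpoint (the mangrove conversion rate, central
  1.9 on 0.7–3.0, is an example), so truncation can be asymmetric.
  Sampling is by inverse CDF of the conditioned distribution, so no draw
  can escape the range and no rejection loop is needed. A degenerate
  range collapses to a point mass.
* **Shifted gamma.** The extent ranges of tidal marsh (2.2–40 Mha,
  central 5.1) and seagrass (17.7–60 Mha, central 30) are heavily
  right-skewed: a minority of very high literature estimates would
  dominate a symmetric reading. These use gamma distributions with the
  published parameters — shape 1.6, scale 6 for marsh; shape 4, scale 4
  for seagrass — translated so support starts at the reported minimum.
  The shift matters: an unshifted gamma(4, 4) has mean 16 Mha, below the
  smallest seagrass extent anyone reports (17.7 Mha), and only the
  shifted variant reproduces the published seagrass median emissions.
  Uniform shifting is therefore the default (`gamma_shift = TRUE`).
* **Lognormal.** Used only by the synthetic oracle generator, never for
  published inputs, because products of independent lognormals have
  closed-form quantiles.

One consequence of uniform shifting is worth stating plainly: the
tidal-marsh emissions median under the default convention is about
0.08–0.09 Pg CO$_2$/yr, while the published central is 0.06, which is
closer to the *unshifted* marsh gamma (~0.064). The two gamma rows of
the published table appear to follow different location conventions; the
package does not try to resolve this and applies one convention
uniformly, with `gamma_shift = FALSE` available. Tidal-marsh statistics
should therefore be read as order-of-magnitude under either setting; the
mangrove (all-normal) and seagrass rows and the totals are robust.

Whether the original normals were truncated at the published range or
only at zero is likewise not documented; range truncation is the default
(`truncation = "range"`), with `truncation = "zero"` as the variant. At
$\pm 2\sigma$ the difference is small (about 5% of the mass per factor).

## Reproducibility

All sampling is driven by one integer seed. Each ecosystem draws from a
private substream whose seed is a deterministic hash of (run seed,
ecosystem name), so per-ecosystem results do not depend on row order and
adding an ecosystem never perturbs the others. Summaries are
bit-identical across runs with equal seed and configuration. Empirical
quantiles use the linear-interpolation convention on order statistics
(`stats::quantile` type 7) so independent implementations agree exactly
on fixed draws.

## Aggregating to the global total

The published total row is the *column sum*: each statistic (lower,
median, upper) summed across the three ecosystems. This is how the
printed components add up (0.24 + 0.45 + 0.33 = 1.02 at the upper
bound), and it is the package default (`aggregation = "column_sum"`).
Statistically, the 90% interval of a sum of independent quantities is
narrower than the sum of the 90% intervals, so the coherent alternative
— summing draws per iteration, then taking percentiles
(`"distribution_sum"`) — is provided and is never wider at the upper
bound. Both are computed from the same retained draws.

## Susceptible density parameterization

The engine samples the susceptible density directly as a truncated
normal over the range (loss$_{\min} \cdot S$, loss$_{central} \cdot S$,
loss$_{\max} \cdot S$), where $S$ is the total per-hectare CO$_2$ stock,
rather than sampling a loss fraction and multiplying a fixed stock. The
two are the same distribution under different names; sampling the
density keeps the three factors symmetric in the engine and in the
sensitivity analysis.

The packaged configuration supplies $S$ directly as the published
per-hectare CO$_2$ values (949, 1492, 522 Mg CO$_2$/ha) through the
optional `total_co2` field. Recomputing from the carbon stocks gives
slightly different numbers because the published table's own conversions
are not internally consistent: no single CO$_2$:C constant reproduces
all three printed values (250 Mg C/ha → printed 917 needs 44/12; 280 →
printed 1028 needs the two-decimal 3.67; 140 → printed 512 matches
neither, as 44/12 gives 513). The package computes with the exact molar
ratio 44/12 everywhere, reports it as 3.67, and documents — rather than
reverse-engineers — the residual ±1 Mg/ha print discrepancies. They are
three orders of magnitude below the propagated uncertainty.

## Reporting rounding

Internal computation never rounds. Report-facing numbers round half away
from zero (`round_half_up()`), the convention under which 932.5 prints
as 933 and 18.45 as 18.5; base R's round-half-to-even would print 932
and 18.4. Emissions are displayed to 2 decimals (Pg CO$_2$/yr), damages
to 1 decimal (billion USD/yr), flux shares to integer percent. Dollar
figures are computed from unrounded emission statistics and rounded
last; computing from pre-rounded emissions changes the upper-bound
damages (1.02 × 41 = 41.8 vs 41.9 from the unrounded 1.021...).

## Sensitivity analysis

`bc_sensitivity()` attributes the spread of the total-emissions
distribution to the nine input factors (3 ecosystems × 3 factors). The
default estimator is first-order and rank-based:

$$ c_i = 100\,(1 - \text{residual})\;
   \frac{\rho_s(X_i, T)^2}{\sum_j \rho_s(X_j, T)^2} $$

with $\rho_s$ the Spearman correlation between factor draws and total
draws, and the residual the share of rank-space variance a first-order
linear fit leaves unexplained. Contributions are nonnegative, a constant
factor contributes exactly zero, and contributions plus residual sum
to 100.

A second mode, `method = "log_variance"`, apportions by
$\mathrm{Var}(\log X_i)$ — exact for a pure product of independent
positive factors, approximate for the three-ecosystem sum. The two modes
answer subtly different questions and disagree on the packaged
configuration in an instructive way: rank correlations measure
association with the realized total, which weights factors of the
dominant ecosystems (mangrove rate and density lead, ~24% and ~23%),
whereas log-variance measures each factor's intrinsic relative spread,
under which the tidal-marsh extent — by far the widest input range, at
roughly a factor of 18 between bounds — leads at ~40%. The latter
matches the qualitative published finding that marsh extent had the
widest influence of any input. No estimator is specified for the
published percentages, so the package asserts only the qualitative
ranking, under the log-variance mode, and reports both decompositions.

## Economic valuation

Damages are emissions times the social cost of carbon (SCC): with
emissions in Pg (billion Mg) and the SCC in dollars per Mg, the product
is directly in billion dollars per year. The default SCC is the central
$41/Mg CO$_2$ (2007 USD) applied to the lower, median, and upper
emission statistics, so the damage interval tracks emissions
uncertainty; the published SCC range ($7–81) is carried in the
configuration for users who want the wider envelope. Reference fluxes
for context — global deforestation emissions (5.5 Pg CO$_2$/yr,
including freshwater peatlands) and the continental-shelf carbon sink
(1.26 Pg CO$_2$/yr) — are packaged for `bc_compare()`.

## What the synthetic generator emulates

`synth_inputs()` generates parameter tables with the structure of the
packaged one — per ecosystem, three independent positive factors each
summarized by `(min, central, max)`, with loss fractions in (0, 1] and
random distribution families — at magnitudes bracketing the coastal
values (extents ~2–60 Mha, rates ~0.4–3 %/yr, stocks ~100–450 Mg C/ha).
It emulates only this statistical structure: factors are independent
within and across ecosystems, ranges are exact, and families are known.
Real inputs violate all three (literature estimates share primary
sources, ranges are themselves uncertain, and the skewness judgment is
qualitative), so passing tests demonstrate correct propagation of the
*assumed* structure, not the realism of the assumptions.

`synth_oracle()` builds cases where the truth is closed-form: three
lognormal factors give exactly lognormal emissions with log-mean
$\sum\mu_i$ and log-sd $\sqrt{\sum\sigma_i^2}$. The engine's empirical
p5/p50/p95 must fall within three asymptotic Monte Carlo standard errors
of the analytic quantiles; the truncated-normal path is additionally
validated against a rejection-sampling oracle and degenerate closed
forms.

## Problem sizes and numerical choices

The validation suite runs the full 50,000-iteration simulation wherever
a published statistic is compared (the Monte Carlo standard error of the
total median is then well under 1%), and 1,500–20,000 iterations for
property checks where only ordering, support, or invariance is at stake.
Twenty oracle cases at 50,000 iterations bound the engine's quantile
error. Degenerate inputs (zero-width ranges) are exact by construction
and tested as equalities; all other stochastic assertions use tolerances
derived from asymptotic standard errors, not tuned constants.

## Limitations

* Temporal dynamics are out of scope: the model estimates committed
  annual emissions from each year's converted area, not the time profile
  of their release.
* CH$_4$/N$_2$O accounting, deep-sediment (>1 m) carbon, lost annual
  sequestration, and spatially explicit mapping are not modelled.
* Factors are treated as independent within and across ecosystems.
* The gamma shape/scale pairs are taken as published; the package does
  not attempt to re-derive them from the ranges, and the two
  gamma-location conventions discussed above remain an acknowledged
  ambiguity affecting the tidal-marsh row.
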