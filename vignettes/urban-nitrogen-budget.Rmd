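---
title: "Accounting for reactive nitrogen in a coupled human-natural urban system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for reactive nitrogen in a coupled human-natural urban system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nflow)
```

## The model

Urban systems concentrate people, industry and energy use, and with them
the creation and loss of reactive nitrogen (Nr): every nitrogen species
other than inert N~2~. `nflow` implements a substance flow analysis (SFA)
of Nr for a city-scale system resolved into twelve subsystems, organised
into four process groups:

* **production** — farmland, urban green, livestock, forest, aquaculture,
  industry;
* **consumption** — the human subsystem;
* **treatment** — sewage disposal and garbage disposal;
* **environment** — atmosphere, surface water, ground water.

New Nr enters the system through biological N fixation (BNF, with
agricultural and natural components), industrial Haber–Bosch fixation
(HBNF), fixation during fossil-fuel combustion, and trade imports. It
leaves by denitrification to N~2~, transfer of reactive species to the
surrounding atmosphere, riverine transfer to the ocean, and trade exports.
Every subsystem is a reservoir obeying conservation of mass for an annual
budget:

$$\sum AC_k \;=\; \sum IN_i \;-\; \sum OUT_j$$

where $IN_i$ and $OUT_j$ are the Nr inputs and outputs of a compartment in
a year and $AC_k$ its stock change (accumulation). Fluxes are stored as
nonnegative magnitudes on directed edges in Gg N y^-1^ (1 Gg = 10^9^ g);
bidirectional exchanges are separate records, so the budget sums stay
trivially interpretable. Years are integer snapshots: there is no
sub-annual dynamics, and no stock is carried between years beyond the
reported accumulation. System-level input and output count only
boundary-crossing flows (external &harr; within-boundary), so internal
recycling never inflates the totals.

```{r}
net <- guangzhou_fixture()$network
system_balance(net, 2015)
```

## The flux grammar

City budgets derive each flux from activity data and parameters: fuel
consumption times an emission factor, product mass times an N content,
population times an excretion rate. `nflow` expresses every such form
through a single declarative grammar: a flux is a **sum of
activity × parameter × scalar terms**, evaluated per year by
`evaluate_flux()`. The grammar is linear by design; if a real flux law
saturates (e.g. volatilization), it must be linearised around the budget
year, which we note as a simplification.

Unit handling is strict. Activities carry mass units (`g`, `kg`, `t`,
`kt`, `Mt`, `Gg`) or dimensionless carriers (`capita`, `head`, `ha`, …);
parameters are either N mass fractions (`frac`, only valid on mass-valued
activities) or rates written `massN/denominator`, whose denominator must
match the activity unit exactly unless both are masses, in which case the
conversion is exact. Any other combination is an error naming the term —
silent unit mistakes are the dominant failure mode of budget models, so
nothing is coerced. Each evaluated flux inherits the *worst* reliability
grade among its contributing activities and parameters, a conservative
choice consistent with the three-grade uncertainty scheme below.

## Uncertainty propagation

Inputs are point estimates with data-quality classes: high, moderate and
low reliability map to coefficients of variation of 0.1, 0.2 and 0.3. A
Monte Carlo trial redraws every activity amount and parameter value
independently from a zero-truncated normal with mean equal to the point
estimate and sd = CV × mean; `propagate()` runs 10,000 trials by default
and reports the ensemble mean, SD, CV and empirical 5th/95th percentiles
(linear interpolation between order statistics).

Choices worth knowing:

* **Distribution family.** The truncated normal matches the CV
  parameterization and keeps fluxes nonnegative. At CV 0.1 the truncation
  is negligible (the 5th/95th percentiles sit at mean ± 1.645 sd); at CV
  0.3 it induces a small upward bias in the mean, which is the price of
  nonnegativity. Truncation is implemented by rejection resampling.
* **Independence.** No correlations between inputs are modelled; where
  activities co-move (e.g. coal and oil use), the ensemble spread of sums
  will be understated. This is a known limitation.
* **Seeding.** One master seed drives a single random stream. Every trial
  draws the full activity *and* parameter deviate vectors in a fixed
  order, whether or not both are applied, so the three runs of
  `decompose_uncertainty()` (activities only, parameters only, both)
  share their randomness and are directly comparable; for a product of
  independent inputs the component variances add to the full variance to
  first order.

A structural property of budget uncertainty falls out of the balance
identity above:
accumulation is a *difference of large sums*, so its relative uncertainty
always exceeds that of the input and output totals it is computed from.
The test suite demonstrates this amplification on the synthetic city.

## Fate indicators

`fate_fractions()` partitions one year's total Nr input into six channels:
denitrified to N~2~, reactive transfer to the surrounding atmosphere,
surface-water transfer to the ocean, trade output, terrestrial
accumulation, and a residual that closes the partition to 100%.
Terrestrial accumulation sums the stock changes of farmland, livestock,
forest, aquaculture, human, ground water and urban green — the atmosphere,
surface water and the treatment subsystems are transit compartments, not
terrestrial stores. Percentages are reported half-away-from-zero at one
decimal (zero decimals where budgets conventionally print integers), and
the unrounded values are always retained alongside, because printed
budget tables routinely differ by one unit in the last digit from ratios
of already-rounded numerators.

Further indicators: `share_of()` (scale-invariant percentage shares),
`nue()` (harvested N over inputs, with a soil-mining warning above 1),
`recycling_ratio()` (excreta N returned to farmland),
`environmental_load_series()` (per-year, per-source NOx, NH~3~, N~2~O and
surface-water discharge series), `input_intensity()` (Gg N over km²
to kg N ha^-1^ y^-1^), and `trace_life_cycle()`, which sums labelled
fluxes stage by stage along the industrial chain (Haber–Bosch fixation,
fossil fuel and imports through agricultural use, trade and waste) or the
food chain (agricultural inputs through human intake to wastewater and
riverine export). The human absorption ratio has no standard denominator
in the literature we follow; compute it with `share_of()` against an
explicitly chosen food-chain input so the choice stays visible.

## Driver decomposition

Anthropogenic Nr creation $I$ (HBNF + fossil-fuel fixation + agricultural
BNF, i.e. excluding only natural BNF) is regressed on socioeconomic
drivers in the STIRPAT form

$$\ln I = a + b\,\ln P + c\,\ln A + d_1\,\ln T_1 + d_2\,\ln T_2 + e$$

with $P$ population, $A$ diet choice (animal-source share of food N
intake, the affluence proxy), $T_1$ energy intensity (energy per unit
GDP) and $T_2$ industrial level (share of Nr creation through
anthropogenic ammonification), both technology proxies. Natural logs are
used throughout; `fit_stirpat()` is ordinary least squares via `lm()`,
with significance stars (0.05/0.01/0.001), variance inflation factors
(via `car::vif()`), and a hard error naming the offending predictors on
perfect collinearity. `screen_factors()` gives the Pearson
correlation/VIF report used to choose candidate drivers; selection itself
is left to the analyst.

Each driver's **annual growth rate** is geometric (CAGR over the full
window): applying the rate as $(1+r)^{\text{coef}}$ strongly implies a
compounding rate, so an arithmetic mean of year-on-year changes would be
inconsistent. Growth rate and elasticity combine into the **effect
coefficient** $EC = (1+r)^{\text{coef}}$ — the driver's multiplicative
annual effect on $I$, greater than 1 exactly when growth and elasticity
share a sign — and effect coefficients into **contribution rates**
$100\,|EC-1| / \sum |EC-1| \times R^2$, which sum to $100 R^2$ by
construction. With ~21 annual observations and four predictors the fit is
small-sample and serially dependent; `fit_stirpat()` therefore also
reports adjusted $R^2$, and a Durbin–Watson check is available through
`lmtest` on the returned model for analysts who want it.

```{r}
d <- simulate_stirpat_data(n = 21, sigma = 0.05, seed = 18)
driver_decomposition(d)
```

## The synthetic city and the fixture

`generate_city()` builds a full 21-year scenario whose activities follow
exponential trends times lognormal noise (positivity is automatic). The
defaults are the study conditions the package assumes: a megacity with
population near 8 million growing 2.35% y^-1^, rising coal, oil, ammonia
production and food imports, fertilizer use and farmland area shrinking
slowly, diet share of animal protein drifting up 0.456% y^-1^, energy
intensity falling 3.53% y^-1^ and industrial level rising 0.364% y^-1^;
activity noise CV 0.03. Magnitudes were chosen once to be plausible for a
south-Chinese megacity (e.g. ~27 Mt coal and ~150 kt ammonia-N by the
final year) and are not revisited. Because every flux is evaluated from
the same activity tables, each yearly network balances per compartment
*by construction* — accumulations absorb the input−output residuals — so
passing conservation tests on the generator demonstrates the ledger
algebra, not the realism of any particular flux. The generator emulates
trends, positivity, graded reliability and the coupling of drivers to
activities; it does **not** emulate cross-input correlations, policy
break-points (such as an abrupt emission-control regime), or reporting
biases of real statistical yearbooks, so tests passing on it say nothing
about those features of real data.

`guangzhou_fixture()` is different in kind: it encodes the *printed*
aggregate fluxes of a published megacity budget (boundary inputs and
outputs for 2015, the handful of internal fluxes the text reports, the
per-compartment accumulations, the 10,000-trial uncertainty table, and
the driver-decomposition inputs), each record carrying a citation string.
The full 12×12 inter-compartment matrix was never published, so the
fixture network does not close per compartment and is excluded from
closure assertions; recorded accumulations travel as their own table. Two
printed inconsistencies are preserved rather than patched: the 1995
totals do not close (142.5 − 99.2 = 43.3 vs the printed 44.7,
presumably rounding of aggregated sub-fluxes), and the surface-water fate
fraction computes to 7.6% where 7.7% is printed. The printed contribution
rates of the driver table (summing to 95.92) are likewise inconsistent
with the stated $R^2$-scaling formula (which yields a sum of 94.0);
`contribution_rates()` implements the formula, and the printed rates are
stored as fixture constants only.

## Numerical choices and edge cases

* Closure tolerance for the ledger identity is 10^-9^ Gg in the working
  precision; in practice it holds to machine epsilon.
* Quantiles use `stats::quantile` type 7 (the R default, linear
  interpolation) so percentile bounds are distribution-free.
* `balance()` on a compartment with no incident fluxes returns zeros with
  a warning rather than failing, since sparse fixture networks legally
  leave compartments untouched.
* Degenerate inputs fail loudly: zero total input for fate fractions,
  nonpositive denominators for shares, NUE and recycling ratios, all-unit
  effect coefficients for contribution rates, nonpositive endpoints for
  growth rates.
* Scenario serialisation writes numbers with 17 significant digits, so a
  write–read–write cycle is byte-identical and re-evaluated indicators
  are unchanged.

## Problem sizes used in the shipped checks

The packaged tests run the conservation property on 1,000 random
networks, the Monte Carlo calibration at 10,000 trials (plus one
100,000-trial moment check), the variance-amplification comparison at
1,000 trials on the 2015 slice of the synthetic city, and the
driver-recovery study as a 100-replicate coverage experiment at n = 100.
These sizes make the whole suite complete in well under a minute on one
core while keeping every statistical tolerance comfortably wide of its
sampling noise.
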