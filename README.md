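# nflow — urban reactive-nitrogen flow accounting

Cities concentrate food demand, industry and fossil-fuel combustion, and
with them the creation and loss of reactive nitrogen (Nr): every N species
other than inert N₂. Quantifying where a city's Nr comes from, how it moves
between subsystems, and where it ends up — the atmosphere, rivers, trade,
or long-lived stocks — is the job of substance flow analysis (SFA). `nflow`
is an R toolkit for that job, written for biogeochemists and urban-ecology
modellers who need a tested, reusable budget pipeline rather than a
one-off spreadsheet.

The package provides:

* **A mass-balance flux network** over twelve within-boundary subsystems
  (farmland, urban green, livestock, forest, aquaculture, industry, human,
  sewage disposal, garbage disposal, atmosphere, surface water, ground
  water) grouped into production / consumption / treatment / environment,
  plus external compartments for trade, the ocean and the surrounding
  atmosphere. Every compartment obeys, per budget year,

  &Sigma; AC&#8342; = &Sigma; IN&#7522; − &Sigma; OUT&#11388;

  (accumulation = inputs − outputs, all in Gg N y⁻¹), and system totals
  count only boundary-crossing flows.
* **A declarative flux engine**: each flux is a sum of
  activity × parameter × scalar terms (fuel × emission factor,
  product × N content, population × excretion rate) with strict unit
  checking and worst-grade reliability propagation.
* **Monte Carlo uncertainty**: reliability grades high/moderate/low map to
  CVs 0.1/0.2/0.3; inputs are redrawn from zero-truncated normals over
  10,000 trials, summarised as mean, SD, CV and 5th/95th percentiles, with
  an activity-vs-parameter decomposition of the variance.
* **Fate indicators**: fate fractions of annual Nr input (denitrified,
  atmospheric transfer, surface-water transfer, trade, terrestrial
  accumulation), input intensities, NUE, excreta recycling ratios,
  per-source emission load series, and life-cycle traces of the industrial
  and food N chains.
* **An extended STIRPAT driver decomposition**:
  ln I = a + b ln P + c ln A + d₁ ln T₁ + d₂ ln T₂ + e, fitted by OLS,
  with effect coefficients EC = (1 + r)^coef and contribution rates
  100·|EC−1|/Σ|EC−1|·R².
* **Data generators**: a seed-deterministic synthetic 21-year city
  scenario, and a fixture encoding the printed 1995/2015 budget of a
  published megacity study, every record carrying its citation string.

## Worked example

The packaged fixture reproduces the printed budget of a Chinese megacity
(7434 km², 1995 and 2015):

```r
library(nflow)
gz <- guangzhou_fixture()

system_balance(gz$network, 2015)
#> $inputs
#> [1] 301.5
#> $outputs
#> [1] 245
#> $accumulation
#> [1] 56.5

fate_fractions(gz$network, 2015)
#> <fate_fractions> year 2015  total input 301.5 Gg N
#>           denitrified_n2     atmospheric_transfer   surface_water_transfer
#>                     23.4                     33.4                      7.6
#>             trade_output terrestrial_accumulation                 residual
#>                     16.8                     18.7                      0.0
```

In words: of the 301.5 Gg N that entered the system in 2015, 23.4% was
denitrified to benign N₂, 33.4% left as reactive species to the
surrounding atmosphere, 7.6% reached the ocean via rivers, 16.8% left
through trade, and 18.7% accumulated in terrestrial subsystems; the
56.5 Gg system accumulation closes the books exactly (301.5 − 245.0).
Input shares and intensities follow the same pattern —
`share_of(111.9, 301.5)` gives the 37.1% import share and
`input_intensity(89.0, 7434)` the 119.7 kg N ha⁻¹ y⁻¹ fossil-fuel
fixation intensity. The driver table's effect coefficients come from the
compound-growth formula:

```r
with(gz$drivers, round(effect_coefficient(growth_rate, coefficient), 3))
#> [1] 1.022 1.012 0.991 1.021
```

i.e. population growth alone multiplied anthropogenic Nr creation by
1.022 per year, diet change by 1.012, falling energy intensity by 0.991
(a brake), and the rising industrial level by 1.021.

For a fully synthetic pipeline run, `generate_city()` builds a 21-year
scenario whose flux network balances by construction;
`propagate(scenario, quantity_balance("farmland", 2015), seed, n_trials)`
then attaches Monte Carlo intervals to any balance component.

## Scope

The package is a flux-bookkeeping and regression toolkit: no atmospheric
chemistry or transport, no water-quality modelling, no spatially explicit
(grid/GIS) budgets, and no sub-annual dynamics. See the methods vignette
(`vignettes/urban-nitrogen-budget.Rmd`) for the model's assumptions,
parameter choices and known limitations.
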