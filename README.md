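# dalyiaq

Population-average chronic health burden of indoor residential air
pollutants, in disability-adjusted life-years (DALYs) lost per 100,000
persons per year.

Indoor residential air carries dozens of pollutants — fine particles,
aldehydes, volatile organics, criteria gases — and comparing them against
each other, or against hazards like radon and secondhand smoke, requires a
metric that combines disease incidence with disease severity. `dalyiaq` is
for exposure scientists and indoor-air-quality analysts who need such
population-level burden estimates, e.g. to assess ventilation standards or
energy-retrofit programs that change indoor concentrations.

## The model

Two parallel chains turn a mean indoor concentration into DALYs:

* **IND (intake–incidence–DALY)**, for the criteria pollutants (PM2.5,
  ozone, NO2, SO2, CO), uses epidemiological concentration–response
  functions. Excess incidence follows the exponential form

  ΔI = −y₀ [exp(−β ΔC) − 1] × population,

  with baseline prevalence y₀, slope β, and exposure increment
  ΔC = 0.70 × C_indoor (the occupancy-weighted share of the day spent at
  home). Incidence times a DALYs-per-incidence factor gives the burden.

* **ID (intake–DALY)**, for noncriteria pollutants, extrapolates directly
  from inhaled mass:

  DALYs = C × V × (CF_cancer × ADAF + CF_noncancer),

  with V ≈ 3,680 m³ of residential air breathed per person-year, CF the
  cancer/noncancer characterization factors (DALY per kg inhaled) and ADAF
  the age-dependent adjustment factor (1.65) applied to the cancer term.
  The characterization-factor database is external; the package ships
  generators that emulate its statistical character for testing.

Uncertainty is propagated by Monte Carlo: DALY factors and incidences are
lognormal (median = central estimate, σ_ln from the 95% CI, or from the
uncertainty factor k = (q97.5/q2.5)^0.5), slopes are zero-truncated
normal. Aligned samples are summed across pollutants for the total, with a
dominance decomposition (how often each pollutant is the largest
contributor). Radon, secondhand smoke (SHS) and acute CO poisoning get
literature-attributed burdens; a threshold-sensitivity module computes the
fraction of predicted burden removed by a no-effect threshold on a
lognormal concentration distribution. See the methods vignette
(`vignettes/indoor-air-daly-methods.Rmd`) for assumptions and parameters.

## Worked example

```r
library(dalyiaq)

demo <- load_fixture_table("demographics")
population_time_at_home(demo)   # 0.7032  (70% of the day at home)
population_intake_rate(demo)    # 14.38   m3/day
annual_residential_volume(demo) # 3680    m3/yr breathed at home

tab <- load_fixture_table("attributed_outcomes")
attributed_dalys(tab, hazard = "SHS", n = 20000, seed = 42)
#> <impact_summary> SHS
#>   median 50.9 (95% CI: 44.2, 62.4) DALY/100k/yr  [n = 20000]
attributed_dalys(tab, hazard = "acute_CO", n = 20000, seed = 42)
#> <impact_summary> acute_CO
#>   median 4.9 (95% CI: 4.71, 5.09) DALY/100k/yr  [n = 20000]
attributed_dalys(tab, hazard = "radon_smoker", n = 20000, seed = 42)
#> <impact_summary> radon_smoker
#>   median 83.9 (95% CI: 25.7, 271) DALY/100k/yr  [n = 20000]
```

Reading: secondhand smoke accounts for a median 51 DALYs lost per 100,000
persons per year (five outcomes, national excess incidences over 3.0e8
persons); acute CO poisoning deaths for 4.9 (1.53 deaths/million × 32
DALYs/death); radon-attributable lung-cancer deaths among smokers for ~84,
with the wide CI reflecting the uncertainty of the attributed death count.

The full two-track pipeline and report:

```r
res <- run_full_pipeline(list(samples = 10000, seed = 42))
write_report(res, "out/")   # ranked per-pollutant CSV + provenance JSON
```

A thin command-line wrapper with subcommands (`ind`, `id`, `attribution`,
`total`, `threshold`, `shs`, `synth`) is installed at
`inst/cli/daly-iaq.R`:

```sh
Rscript inst/cli/daly-iaq.R threshold --pollutant Formaldehyde \
    --mean 69 --gsd 2.5 --threshold 120 --mode excess
# Formaldehyde: 80.9% reduction in predicted DALY losses (threshold 120 ug/m3, excess mode)
```

## Input tables

CSV fixtures under `inst/extdata/` (UTF-8, one header row): pollutant mean
indoor concentrations (`concentrations.csv`: pollutant, mean_ugm3), C-R
parameters (`cr_functions.csv`: pollutant, outcome, beta, beta_lo, beta_hi,
y0, form, daly, daly_lo, daly_hi, flag; stroke complication strata in
`stroke_strata.csv`), residential occupancy demographics
(`demographics.csv`: label, population_fraction, adaf, time_at_home,
intake_m3_day) and attributed outcomes (`attributed_outcomes.csv`: hazard,
outcome, incidence with CI, rate_basis, daly with CI). Outputs are always
labeled `DALY/100k/yr`.
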