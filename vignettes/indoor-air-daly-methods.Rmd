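---
title: "Estimating the chronic DALY burden of indoor residential air pollutants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the chronic DALY burden of indoor residential air pollutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dalyiaq)
```

## The problem and the metric

Americans spend roughly 70% of their time inside residences, and indoor air
carries dozens of pollutants — combustion particles, aldehydes emitted by
building materials, volatile organics, criteria gases — at concentrations
that in many homes exceed chronic health guidelines. Comparing such
heterogeneous hazards, and comparing indoor air as a whole against other
environmental health risks, requires a single metric that reflects both how
often a pollutant makes people ill and how bad the illness is. That metric is
the disability-adjusted life-year (DALY): years of life lost to premature
mortality plus severity-weighted years lived with disability, so that one
DALY is one lost year of healthy life. All results in this package are
expressed as DALYs lost per 100,000 persons per year.

`dalyiaq` estimates the population-average chronic burden of inhaling indoor
residential air pollutants through two parallel model chains, propagates
input uncertainty by lognormal Monte Carlo, and adds literature-based
attribution for three hazards that the chains cannot treat mechanistically
(radon, secondhand smoke as a whole, acute CO poisoning).

## The two model chains

**IND (intake–incidence–DALY), for criteria pollutants.** Human epidemiology
supplies concentration–response (C-R) functions for PM2.5, ozone, NO2, SO2
and CO. For almost all outcomes the excess incidence takes the exponential
form

$$\Delta I = -y_0\,\left[e^{-\beta\,\Delta C} - 1\right] \times \mathrm{population},$$

where $y_0$ is the baseline annual prevalence of the outcome, $\beta$ the
slope per unit of exposure-concentration increment, and $\Delta C$ the
increment itself. The form is linear for small $\beta \Delta C$ and
saturates at $y_0 \times \mathrm{population}$. Excess incidence is then
multiplied by a DALYs-per-incidence factor for the outcome. Because the C-R
functions act on *exposure* concentration while the inputs are *indoor*
concentrations, the increment is scaled by residential occupancy:
$\Delta C = 0.70 \times C_\mathrm{indoor}$ with the packaged demographics.

Two special cases: the NO2 respiratory-illness response is published as a
slope with uncertainty but no baseline prevalence, so it is evaluated with
the first-order (linearized) form with $y_0$ taken as 1 — the slope is read
directly as an incidence rate per unit concentration — and the assumption is
flagged in the result metadata. Nonfatal stroke severity depends on
complication count, so stroke incidence is split across the 0 / 1 / >1
complication strata (central DALY factors 9.5 / 11.7 / 13.1 per case). The
split weights are not published; the default is equal thirds, exposed as a
parameter, and the total is insensitive to the choice (the strata differ by
under 40%).

**ID (intake–DALY), for the noncriteria pollutants.** Toxicology-based
characterization factors map inhaled mass directly to DALYs:

$$\mathrm{DALYs} = C_i \times V \times
  \left(CF_{i,\mathrm{cancer}} \times \mathrm{ADAF} + CF_{i,\mathrm{noncancer}}\right),$$

with $C_i$ the indoor concentration, $V$ the volume of residential air
breathed per person-year, and $CF$ in DALYs per kg inhaled (the µg→kg
conversion, 1e-9, is applied once, inside `id_dalys_point()`). The
age-dependent adjustment factor (ADAF) inflates cancer potency for
early-life exposure and multiplies the cancer term only.

Ozone is the one pollutant both chains can treat; the pipeline sends it
through the preferred IND chain in the total and reports the ID estimate
alongside for the dual-track comparison.

## Exposure machinery and its parameters

The demographics table has three age bins (under 2 / 2–16 / over 16) with
population fractions 0.03 / 0.19 / 0.78, ADAFs 10 / 3 / 1, time at home
0.75 / 0.75 / 0.69 and breathing rates 7 / 13 / 15 m³/day. Population
averages are convex combinations of the bin values: time at home 0.7032
(reported as 70%), intake 14.38 m³/day (14.4), ADAF 1.65 (1.6 after
rounding).

The annual residential breathing volume $V$ is computed *group-wise* —
$\sum_g f_g \cdot \mathrm{intake}_g \cdot \mathrm{time}_g \cdot 365 \approx
3{,}680$ m³/yr — not as the product of the two population averages, because
intake and occupancy are correlated across age groups ($V$ is an
individual-level quantity aggregated over people). On this table the two
differ by under 0.5%. Days per year is fixed at 365.

Whether the published population-average ADAF of 1.6 is population-weighted
(1.65) or intake-and-time-weighted (≈1.46) is not determinable from the
rounded value; `population_adaf()` defaults to population weighting and
exposes `weighting = "intake_time"` as the alternative.

## Uncertainty model

Every uncertain input carries a central estimate and a 95% CI. The
conventions, applied uniformly:

* **DALY factors, characterization factors, attributed incidences:
  lognormal**, median equal to the printed central estimate and
  $\sigma_{\ln} = \ln(q_{97.5}/q_{2.5}) / (2 \times 1.96)$. When the printed
  central is inconsistent with the geometric midpoint of its CI (the radon
  nonsmoker incidence is strongly asymmetric), the printed central still
  wins as the median, on the reading that it is the central estimate.
* **C-R slopes: normal**, mean at the central value,
  $\sigma = (\mathrm{CI\ width})/(2 \times 1.96)$, truncated at zero by
  inverse-CDF on the renormalized upper tail (no probability atom at zero).
  The distribution family for slopes is a package choice; published CIs for
  regression coefficients are conventionally symmetric.
* **ID-factor uncertainty** is parameterized by the factor
  $k = (q_{97.5}/q_{2.5})^{1/2}$, so median/k and median×k recover the 95%
  interval and $\sigma_{\ln} = \ln(k)/1.96$; $k = 1$ collapses to a point
  mass.

Monte Carlo draws are parametric and independent across pollutants and
across the cancer/noncancer factor pair (no joint uncertainty structure is
published). Default n is 10,000 samples and the default seed 42; fixed
seeds give bit-identical results on one platform. Per-pollutant sample
vectors from one run are index-aligned, so the total burden is the exact
element-wise sum, and the dominance decomposition (fraction of samples in
which each pollutant is the largest contributor; ties to the first-listed,
a measure-zero event) and super-threshold share statistics are computed per
sample. Central estimates and CIs are the empirical 50th / 2.5th / 97.5th
percentiles with type-7 linear interpolation.

One input is internally inconsistent as printed: the PM2.5 total-mortality
slope is 0.058 with CI (0.002, 0.010), a central value outside its own CI
(plausibly a per-10-µg/m³ vs per-µg/m³ transcription issue in the source
table). The table is stored as printed with a flag; fitting proceeds with
the printed central as the location and the CI width as the spread, and the
fallback is logged exactly once per run. Slope units for the gaseous
pollutants are likewise unstated; the package assumes per µg/m³ throughout,
matching the concentration table's units, and tags every IND result with
that assumption. Both issues mean the absolute IND levels for PM2.5 and the
gases carry an unresolved scale uncertainty; the relative structure and the
attribution results do not.

## Literature-based attribution

For radon, SHS and acute CO poisoning the package multiplies attributed
excess incidences by DALYs-per-incidence factors (the same identity the IND
chain uses, with incidence taken from the literature instead of a C-R
function). National counts divide by the population (default 3.0×10⁸
persons, which reproduces the published SHS arithmetic of 51 DALY/100k/yr);
the acute-CO record is a per-million death rate and rescales directly
(1.53 × 32 / 10 = 4.9). The SIDS factor is fixed at 78 DALYs per case
(a current-life-expectancy value) with no uncertainty; per-1,000-case
factors are stored as per-case decimals.

The radon point arithmetic gives 84 (smokers) and 14 (nonsmokers)
DALY/100k/yr, about 6–8% above the published Monte Carlo medians of 79
and 13; the source's exact population constant or distribution choice is
not recoverable, so the discrepancy is documented rather than tuned away.

The component-based SHS cross-check runs the concentration increments of a
smoking household through the two chains (PM2.5 +16 µg/m³ through IND, the
VOC components through ID) and scales by the fraction of homes with smokers
(default 0.11). Component-resolved VOC increments are not packaged; the
default stand-in sets each listed VOC's increment equal to its baseline
residential concentration (the published observation that a smoker roughly
doubles indoor PM2.5 and acrolein, generalized), and is labelled synthetic.

## Threshold sensitivity

The burden chains are no-threshold linear models, so only the mean
concentration enters. If a pollutant actually has a no-effect threshold
$T$, the predicted burden falls by a fraction computable from the
residential concentration *distribution*, taken lognormal and
parameterized by arithmetic mean and geometric standard deviation (GSD),
the exposure literature's reporting style. Two readings are implemented,
both by closed-form lognormal partial expectations and cross-checked
against adaptive quadrature to 1e-6:

* `excess`: only the super-threshold excess harms —
  $1 - E[(C-T)^+]/E[C]$ (the default; a no-effect threshold most naturally
  zeroes the sub-threshold increment);
* `truncation`: sub-threshold homes contribute nothing, super-threshold
  homes their full concentration — $1 - E[C\,1\{C>T\}]/E[C]$.

Since $(C-T)^+ \le C\,1\{C>T\}$ pointwise, the excess-mode reduction always
dominates. Published reduction figures for formaldehyde (32% at 12 µg/m³,
87% at 120 µg/m³) and acrolein (20% at 0.35 µg/m³) come with no GSD, so
they are calibration references rather than reproducible targets;
`calibrate_gsd()` inverts the computation by monotone root search to
explore which distributions are consistent with them.

## Synthetic data: what it emulates and what it does not

The ID chain's characterization-factor database is external and not
redistributed; `generate_id_factors()` emulates only its statistical
character — factors log-uniform over orders of magnitude (default 1e-4 to
1e2 DALY/kg, chosen so that typical residential concentrations produce
per-pollutant impacts spanning roughly 1e-2 to 1e2 DALY/100k/yr) with k
log-uniform over 10–100. Generated values carry no per-pollutant
toxicological meaning, so passing tests demonstrate that the machinery
(sampling, aggregation, dominance, reporting) is correct, not that any
specific noncriteria pollutant's absolute burden is right. Published
per-pollutant ID results and the published aggregate total are therefore
not numerical targets of this package; the quantities that are exactly or
stochastically reproducible from packaged inputs are the occupancy
averages, the acute CO and SHS attribution, and the radon Monte Carlo
medians.

`generate_recovery_scenario()` builds scenarios with *known* analytic
structure (prescribed expected impact shares; the lognormal mean–median
offset $e^{\sigma_{\ln}^2/2}$ is divided out so the analytic total equals
the Monte Carlo mean) for parameter-recovery testing of the dominance
statistics.

## Numerical choices and degenerate inputs

* Empirical quantiles: type-7 (R default, linear interpolation); a
  two-point vector (1, 3) has median 2.
* Degenerate uncertainty (k = 1, collapsed CIs, `degenerate = TRUE`)
  reduces every Monte Carlo chain to its closed-form point value exactly —
  this is the main end-to-end correctness oracle.
* Zero concentrations, zero incidences and zero thresholds propagate to
  exact zeros; thresholds of ∞ give reduction 1.
* Validation is fail-fast at load: inverted CIs, fractions outside [0,1],
  ADAF < 1, k < 1 and population fractions not summing to 1 (tolerance
  0.01) are rejected.
* Problem sizes: tests use 10,000 Monte Carlo samples where a published
  statistic is compared (with brute-force oracle runs of 5×10⁵–10⁶ draws)
  and smaller n where only determinism or algebraic structure is checked;
  the acceptance script uses 50,000 samples. These sizes put Monte Carlo
  error on the median well below the comparison tolerances.

## Known limitations

* Acute and short-term endpoints, nonlinear C-R forms, biological
  contaminants and bromomethane are out of scope by design.
* The β-unit ambiguity above means IND levels for the criteria gases are
  conditional on the per-µg/m³ reading.
* Radon DALYs for smokers are attributed entirely to radon although part
  of the joint radon–smoking burden would occur from smoking alone; no
  interaction correction is applied.
* Cross-pollutant correlations in concentrations or factors are not
  modelled; CIs on the total would widen under positive correlation.
* The three-bin demographics abstraction ignores activity patterns and
  regional variation.
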