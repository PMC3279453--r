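Package: dalyiaq
Title: Chronic Health Burden of Indoor Residential Air Pollutants in DALYs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the population-average chronic health burden, in
    disability-adjusted life-years (DALYs) lost per 100,000 persons per year,
    from inhalation of air pollutants in U.S. residences. Two parallel
    modelling tracks are provided: an epidemiology-based intake-incidence-DALY
    (IND) chain that applies exponential concentration-response functions and
    literature DALYs-per-incidence factors to criteria pollutants, and a
    toxicology-based intake-DALY (ID) chain that extrapolates directly from
    mass intake to DALYs via cancer and noncancer characterization factors
    with age-dependent adjustment. Uncertainty is propagated by lognormal
    Monte Carlo sampling; literature-based attribution is included for radon,
    secondhand smoke and acute carbon monoxide poisoning, together with a
    no-effect-threshold sensitivity analysis on lognormal concentration
    distributions and synthetic-data generators for the toxicological factor
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
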