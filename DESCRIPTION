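Package: cycleimpacts
Title: Scenario Modelling of Cycling Uptake and Its Transport, Carbon and Health Impacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-level scenario engine for modelling increases in
    regular cycling from one-week travel-diary data. Non-cyclists are
    converted to regular cyclists by quota (with or without age/gender
    equity), and their trips are switched to cycling or e-biking according
    to the distance-band propensity observed among current cyclists. The
    package quantifies transport impacts (mode share, miles cycled, car
    miles, journey-time changes), car CO2-equivalent emissions, physical
    activity in marginal MET-hours per week (fusing travel and non-travel
    activity), and premature-mortality burden averted via a comparative
    risk assessment with individual-level exposures and population impact
    fractions applied to years-of-life-lost tables. Seeded synthetic-data
    generators emulate the statistical structure of the travel-diary,
    activity-survey, e-bike reference and disease-burden inputs so the
    full pipeline runs without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
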