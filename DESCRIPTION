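Package: livesaved
Title: Scenario Modelling of Child Mortality Impact from Health Intervention Scale-Up
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates cause-specific and all-cause reductions in under-five
    mortality that result from scaling up the coverage of maternal and child
    health interventions. Direct effects are computed from intervention
    effectiveness, affected fractions and coverage change, composed
    multiplicatively on residual mortality and attributed to interventions by
    the timing of their action. Vaccines and bednets can carry a piecewise
    linear herd-protection curve. Nutrition and environmental interventions
    act indirectly through intermediate outcomes (stunting, severe wasting,
    intra-uterine growth restriction, diarrhoea incidence and breastfeeding
    practice) using odds-ratio prevalence decompositions and relative-risk
    weighted z-score band distributions. A simplified cohort engine carries
    annual birth cohorts through five age bands to report deaths, deaths
    averted by cause and by intervention, and mortality rates per year.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
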