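# Independent bisection oracle for the two-status odds-ratio decomposition:
# solves the mixture constraint for the non-risky prevalence without the
# closed-form quadratic used by the implementation.
bisect_two_state <- function(odds_ratio, risky_fraction, prevalence,
                             tol = 1e-12) {
  f <- function(p1) {
    pk <- odds_ratio * p1 / (1 - p1 + odds_ratio * p1)
    risky_fraction * pk + (1 - risky_fraction) * p1 - prevalence
  }
  lo <- 1e-12
  hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  p1 <- (lo + hi) / 2
  list(p_nonrisky = p1,
       p_risky = odds_ratio * p1 / (1 - p1 + odds_ratio * p1))
}

# Residuals of the defining relations of the two-status decomposition.
two_state_residuals <- function(sol, odds_ratio, risky_fraction, prevalence) {
  odds_rel <- sol$p_risky -
    odds_ratio * sol$p_nonrisky /
      (1 - sol$p_nonrisky + odds_ratio * sol$p_nonrisky)
  mix <- risky_fraction * sol$p_risky +
    (1 - risky_fraction) * sol$p_nonrisky - prevalence
  c(odds_rel, mix)
}

# Minimal one-intervention scenario used for closed-form cohort checks:
# neonatal diarrhoea only, configurable reduction at the final year.
tiny_scenario <- function(reduction = 0.466, births = 1000,
                          neonatal_risk = 0.03, diarrhoea_fraction = 0.2,
                          years = 2010:2011) {
  mk_band <- function(risk, period) {
    if (period == "neonatal") {
      cf <- c(diarrhoea = diarrhoea_fraction, other = 1 - diarrhoea_fraction)
    } else {
      cf <- c(diarrhoea = diarrhoea_fraction, other = 1 - diarrhoea_fraction)
    }
    list(risk = risk, cause_fractions = cf)
  }
  scenario(
    name = "tiny",
    baseline_year = years[1], final_year = years[length(years)],
    births = births,
    mortality = list(
      "0m" = mk_band(neonatal_risk, "neonatal"),
      "1-5m" = mk_band(0.01, "post"),
      "6-11m" = mk_band(0.01, "post"),
      "12-23m" = mk_band(0.005, "post"),
      "24-59m" = mk_band(0.006, "post")
    ),
    interventions = list(
      intervention("combo", "curative-after-birth",
        effects = data.frame(cause = "diarrhoea", age_band = "0m",
                             effectiveness = reduction,
                             affected_fraction = 1,
                             stringsAsFactors = FALSE))
    ),
    coverage = data.frame(
      intervention = "combo", year = years,
      coverage = seq(0, 1, length.out = length(years)),
      stringsAsFactors = FALSE)
  )
}
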