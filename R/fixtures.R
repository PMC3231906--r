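linear_coverage <- function(id, years, c0, ct) {
  data.frame(intervention = id, year = years,
             coverage = seq(c0, ct, length.out = length(years)),
             stringsAsFactors = FALSE)
}

demo_relative_risks <- function() {
  rows <- list()
  add <- function(factor, category, cause, age_band, rr) {
    rows[[length(rows) + 1L]] <<- expand.grid(
      factor = factor, category = category, cause = cause,
      age_band = age_band, rr = rr, stringsAsFactors = FALSE)
  }
  zb <- z_band_labels()
  stunt_rr <- list(  # anchored on severe stunting vs diarrhoea at 1-5m (4.6)
    diarrhoea = c(4.6, 2.1, 1.4, 1.0),
    pneumonia = c(4.0, 2.0, 1.3, 1.0),
    measles   = c(3.0, 1.8, 1.2, 1.0),
    malaria   = c(2.5, 1.6, 1.2, 1.0)
  )
  for (cs in names(stunt_rr)) {
    for (k in seq_along(zb)) {
      add("stunting", zb[k], cs, POSTNEONATAL_BANDS, stunt_rr[[cs]][k])
    }
  }
  wast_rr <- c(6.0, 2.5, 1.5, 1.0)
  for (cs in c("diarrhoea", "pneumonia")) {
    for (k in seq_along(zb)) {
      add("wasting", zb[k], cs, POSTNEONATAL_BANDS, wast_rr[k])
    }
  }
  for (cs in c("sepsis/pneumonia", "prematurity", "diarrhoea")) {
    add("iugr", "iugr", cs, "0m",
        c(`sepsis/pneumonia` = 2.0, prematurity = 2.5, diarrhoea = 1.8)[[cs]])
    add("iugr", "normal", cs, "0m", 1.0)
  }
  bf_rr <- c(exclusive = 1.0, predominant = 1.5, partial = 2.5, none = 4.0)
  for (cs in c("diarrhoea", "pneumonia")) {
    for (ctg in names(bf_rr)) {
      add("breastfeeding", ctg, cs, c("0m", "1-5m", "6-11m"), bf_rr[[ctg]])
    }
  }
  do.call(rbind, rows)
}

#' Worked-example scenario bundle
#'
#' A small, fully self-consistent scenario whose interventions carry the
#' canonical textbook parameter values of the model: ORS (effectiveness
#' 0.93, affected fraction 0.95, coverage 25% to 50%), zinc for treatment
#' (isolated reduction 0.25 at full scale-up), rotavirus vaccine (vaccines
#' tier, isolated reduction 0.306), measles vaccine (effectiveness 0.85
#' with the 0.90/0.95/1.0 herd curve, coverage 75% to 97%), preventive zinc
#' (stunting odds ratio 1.18, coverage 25% to 50%) and a hand-washing
#' intervention that cuts diarrhoea incidence from 3 to 2 episodes per year
#' at full scale-up, plus complementary feeding, supplemental feeding,
#' breastfeeding promotion and an IUGR-reducing pregnancy intervention.
#' Relative-risk values outside the published anchors are synthetic demo
#' values. Coverage trajectories are linear over 2010-2015.
#'
#' @return An `impact_scenario` that passes [validate_scenario()].
#' @export
demo_scenario <- function() {
  years <- 2010:2015
  ivs <- list(
    intervention("ors", "curative-after-birth",
      effects = data.frame(cause = "diarrhoea", age_band = POSTNEONATAL_BANDS,
                           effectiveness = 0.93, affected_fraction = 0.95,
                           stringsAsFactors = FALSE)),
    intervention("zinc_treatment", "curative-after-birth",
      effects = data.frame(cause = "diarrhoea", age_band = POSTNEONATAL_BANDS,
                           effectiveness = 0.25, affected_fraction = 1,
                           stringsAsFactors = FALSE)),
    intervention("rotavirus_vaccine", "vaccines",
      effects = data.frame(cause = "diarrhoea", age_band = POSTNEONATAL_BANDS,
                           effectiveness = 0.306, affected_fraction = 1,
                           stringsAsFactors = FALSE)),
    intervention("measles_vaccine", "vaccines",
      effects = data.frame(cause = "measles", age_band = POSTNEONATAL_BANDS,
                           effectiveness = 0.85, affected_fraction = 1,
                           herd = TRUE, stringsAsFactors = FALSE),
      herd_curve = herd_curve(0.90, 0.95, 1.0)),
    intervention("zinc_preventive", "preventive-after-birth",
      risk_factor_effects = list(
        list(factor = "stunting", odds_ratio = 1.18))),
    intervention("hand_washing", "preventive-after-birth",
      risk_factor_effects = list(
        list(factor = "diarrhoea_incidence", effectiveness = 1 / 3,
             affected_fraction = 1))),
    intervention("complementary_feeding", "preventive-after-birth",
      risk_factor_effects = list(
        list(factor = "stunting_feeding",
             odds_ratios = c(1.2, 1.5, 2.0)))),
    intervention("supplemental_feeding", "preventive-after-birth",
      risk_factor_effects = list(
        list(factor = "wasting",
             destination_split = c(above_m1 = 0.2, m2_to_m1 = 0.3,
                                   m3_to_m2 = 0.3, stay = 0.2)))),
    intervention("bf_promotion", "preventive-after-birth",
      risk_factor_effects = list(
        list(factor = "breastfeeding", odds_ratio = 0.6))),
    intervention("ipt_pregnancy", "pregnancy",
      risk_factor_effects = list(
        list(factor = "iugr", effectiveness = 0.2, affected_fraction = 1)))
  )
  coverage <- rbind(
    linear_coverage("ors", years, 0.25, 0.50),
    linear_coverage("zinc_treatment", years, 0, 1),
    linear_coverage("rotavirus_vaccine", years, 0, 1),
    linear_coverage("measles_vaccine", years, 0.75, 0.97),
    linear_coverage("zinc_preventive", years, 0.25, 0.50),
    linear_coverage("hand_washing", years, 0, 1),
    linear_coverage("complementary_feeding", years, 0.30, 0.60),
    linear_coverage("supplemental_feeding", years, 0, 0.50),
    linear_coverage("bf_promotion", years, 0.20, 0.60),
    linear_coverage("ipt_pregnancy", years, 0, 0.50)
  )
  mortality <- list(
    "0m" = list(risk = 0.030, cause_fractions = c(
      "birth asphyxia" = 0.23, prematurity = 0.28, "sepsis/pneumonia" = 0.25,
      "congenital anomalies" = 0.07, tetanus = 0.02, diarrhoea = 0.02,
      other = 0.13)),
    "1-5m" = list(risk = 0.015, cause_fractions = c(
      diarrhoea = 0.20, pneumonia = 0.25, meningitis = 0.04, measles = 0.05,
      malaria = 0.15, pertussis = 0.03, injury = 0.03, other = 0.25)),
    "6-11m" = list(risk = 0.012, cause_fractions = c(
      diarrhoea = 0.20, pneumonia = 0.25, meningitis = 0.04, measles = 0.05,
      malaria = 0.15, pertussis = 0.03, injury = 0.03, other = 0.25)),
    "12-23m" = list(risk = 0.010, cause_fractions = c(
      diarrhoea = 0.20, pneumonia = 0.22, meningitis = 0.04, measles = 0.08,
      malaria = 0.18, pertussis = 0.02, injury = 0.05, other = 0.21)),
    "24-59m" = list(risk = 0.012, cause_fractions = c(
      diarrhoea = 0.20, pneumonia = 0.18, meningitis = 0.03, measles = 0.08,
      malaria = 0.20, pertussis = 0.01, injury = 0.08, other = 0.22))
  )
  risk_factors <- list(
    stunting = list(
      prevalence = c("0m" = 0.18, "1-5m" = 0.28, "6-11m" = 0.35,
                     "12-23m" = 0.40, "24-59m" = 0.42),
      carryover_odds_ratio = 5.0,
      iugr_odds_ratio = 2.5,
      diarrhoea_odds_ratio_per_episode = 1.08,
      food_secure_fraction = 0.55),
    severe_wasting = list(
      prevalence = c("0m" = 0.02, "1-5m" = 0.03, "6-11m" = 0.04,
                     "12-23m" = 0.04, "24-59m" = 0.03)),
    iugr = list(fraction = 0.15),
    diarrhoea = list(episodes = c("1-5m" = 3, "6-11m" = 4, "12-23m" = 4,
                                  "24-59m" = 2)),
    breastfeeding = list(
      fractions = list(
        "0m" = c(exclusive = 0.40, predominant = 0.25, partial = 0.25,
                 none = 0.10),
        "1-5m" = c(exclusive = 0.30, predominant = 0.25, partial = 0.30,
                   none = 0.15),
        "6-11m" = c(exclusive = 0.05, predominant = 0.15, partial = 0.60,
                    none = 0.20)),
      improved = list("0m" = "exclusive", "1-5m" = "exclusive",
                      "6-11m" = c("exclusive", "predominant", "partial")))
  )
  scenario(
    name = "worked-examples",
    baseline_year = 2010, final_year = 2015,
    births = 100000,
    mortality = mortality,
    interventions = ivs,
    coverage = coverage,
    risk_factors = risk_factors,
    relative_risks = demo_relative_risks()
  )
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

random_cause_fractions <- function(period) {
  ct <- causes_table()
  cs <- ct$cause[ct$period == period & !ct$is_residual]
  resid <- stats::runif(1, 0.15, 0.30)
  w <- stats::rgamma(length(cs), shape = 2)
  f <- stats::setNames(w / sum(w) * (1 - resid), cs)
  f["other"] <- 1 - sum(f)
  f
}

#' Generate a synthetic country scenario
#'
#' Draws an internally consistent scenario — baseline mortality, cause
#' fractions (residual absorbing the remainder), monotone coverage
#' trajectories, risk-factor baselines and relative-risk tables — from a
#' seeded generator. The same seed always yields an identical bundle. The
#' first interventions exercise every indirect route (stunting, feeding,
#' wasting, breastfeeding, IUGR, diarrhoea incidence); the remainder act
#' directly on randomly chosen cause/band cells, with occasional herd-capable
#' vaccines.
#'
#' @param seed Integer seed.
#' @param n_interventions Number of interventions (>= 6).
#' @param n_years Projection length in years including the baseline year.
#' @param flat If `TRUE`, all trajectories stay at baseline coverage (a
#'   null scenario: zero impact everywhere).
#' @return An `impact_scenario` that passes [validate_scenario()].
#' @export
random_country_scenario <- function(seed, n_interventions = 20,
                                    n_years = 15, flat = FALSE) {
  stopifnot(n_interventions >= 6)
  with_seed(seed, {
    base <- 2010L
    final <- base + n_years - 1L
    years <- base:final
    ct <- causes_table()
    active_post <- ct$cause[ct$period == "postneonatal" & !ct$is_residual &
                              ct$active]
    active_neo <- ct$cause[ct$period == "neonatal" & !ct$is_residual]

    mortality <- list(
      "0m" = list(risk = stats::runif(1, 0.02, 0.04),
                  cause_fractions = random_cause_fractions("neonatal")))
    for (b in POSTNEONATAL_BANDS) {
      mortality[[b]] <- list(risk = stats::runif(1, 0.005, 0.02),
                             cause_fractions = random_cause_fractions("postneonatal"))
    }

    ivs <- list()
    cov <- list()
    add_iv <- function(iv, c0 = NULL, ctv = NULL) {
      ivs[[length(ivs) + 1L]] <<- iv
      c0 <- c0 %||% stats::runif(1, 0, 0.5)
      ctv <- if (flat) c0 else ctv %||% (c0 + stats::runif(1) * (1 - c0))
      cov[[length(cov) + 1L]] <<- linear_coverage(iv$id, years, c0, ctv)
    }
    add_iv(intervention("zinc_preventive", "preventive-after-birth",
      risk_factor_effects = list(list(factor = "stunting",
                                      odds_ratio = stats::runif(1, 1.05, 1.6)))))
    add_iv(intervention("hand_washing", "preventive-after-birth",
      risk_factor_effects = list(list(factor = "diarrhoea_incidence",
                                      effectiveness = stats::runif(1, 0.1, 0.4),
                                      affected_fraction = 1))))
    add_iv(intervention("complementary_feeding", "preventive-after-birth",
      risk_factor_effects = list(list(factor = "stunting_feeding",
                                      odds_ratios = sort(stats::runif(3, 1.1, 2.5))))))
    add_iv(intervention("supplemental_feeding", "preventive-after-birth",
      risk_factor_effects = list(list(factor = "wasting",
        destination_split = local({
          w <- stats::rgamma(4, 2); stats::setNames(w / sum(w),
            c("above_m1", "m2_to_m1", "m3_to_m2", "stay"))
        })))))
    add_iv(intervention("bf_promotion", "preventive-after-birth",
      risk_factor_effects = list(list(factor = "breastfeeding",
                                      odds_ratio = stats::runif(1, 0.5, 0.9)))))
    add_iv(intervention("ipt_pregnancy", "pregnancy",
      risk_factor_effects = list(list(factor = "iugr",
                                      effectiveness = stats::runif(1, 0.1, 0.3),
                                      affected_fraction = 1))))
    for (k in seq_len(n_interventions - 6L)) {
      tier <- sample(timing_tiers(), 1)
      neonatal <- stats::runif(1) < 0.3
      causes <- sample(if (neonatal) active_neo else active_post,
                       sample(1:2, 1))
      bds <- if (neonatal) NEONATAL_BAND else
        sample(POSTNEONATAL_BANDS, sample(2:4, 1))
      eff <- expand.grid(cause = causes, age_band = bds,
                         stringsAsFactors = FALSE)
      eff$effectiveness <- stats::runif(nrow(eff), 0.1, 0.9)
      eff$affected_fraction <- stats::runif(nrow(eff), 0.5, 1)
      hc <- NULL
      if (identical(tier, "vaccines") && stats::runif(1) < 0.5) {
        eff$herd <- TRUE
        hc <- herd_curve(0.85, 0.95, stats::runif(1, 0.5, 1))
      }
      add_iv(intervention(sprintf("iv%02d", k), tier, effects = eff,
                          herd_curve = hc))
    }

    risk_factors <- list(
      stunting = list(
        prevalence = stats::setNames(
          sort(stats::runif(5, 0.15, 0.45)), band_labels()),
        carryover_odds_ratio = stats::runif(1, 3, 8),
        iugr_odds_ratio = stats::runif(1, 1.5, 3),
        diarrhoea_odds_ratio_per_episode = stats::runif(1, 1.02, 1.12),
        food_secure_fraction = stats::runif(1, 0.3, 0.7)),
      severe_wasting = list(prevalence = stats::setNames(
        stats::runif(5, 0.01, 0.06), band_labels())),
      iugr = list(fraction = stats::runif(1, 0.08, 0.2)),
      diarrhoea = list(episodes = stats::setNames(
        stats::runif(4, 1.5, 5), POSTNEONATAL_BANDS)),
      breastfeeding = list(
        fractions = lapply(stats::setNames(nm = c("0m", "1-5m", "6-11m")),
          function(b) {
            w <- stats::rgamma(4, 2)
            stats::setNames(w / sum(w),
                            c("exclusive", "predominant", "partial", "none"))
          }),
        improved = list("0m" = "exclusive", "1-5m" = "exclusive",
                        "6-11m" = c("exclusive", "predominant", "partial")))
    )

    scenario(
      name = sprintf("synthetic-country-%d", seed),
      baseline_year = base, final_year = final,
      births = 100000,
      mortality = mortality,
      interventions = ivs,
      coverage = do.call(rbind, cov),
      risk_factors = risk_factors,
      relative_risks = demo_relative_risks()
    )
  })
}
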