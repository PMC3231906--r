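#' Age bands of the under-five period
#'
#' The model follows children through five age bands that partition the first
#' 60 months of life: 0 months (neonatal), 1-5 months, 6-11 months,
#' 12-23 months and 24-59 months. End months are exclusive.
#'
#' @return A data frame with columns `label`, `start_months`, `end_months`
#'   (exclusive) and `duration_years`.
#' @export
#' @examples
#' age_bands()
age_bands <- function() {
  data.frame(
    label = c("0m", "1-5m", "6-11m", "12-23m", "24-59m"),
    start_months = c(0L, 1L, 6L, 12L, 24L),
    end_months = c(1L, 6L, 12L, 24L, 60L),
    duration_years = c(1, 5, 6, 12, 36) / 12,
    stringsAsFactors = FALSE
  )
}

#' @rdname age_bands
#' @export
band_labels <- function() age_bands()$label

NEONATAL_BAND <- "0m"
POSTNEONATAL_BANDS <- c("1-5m", "6-11m", "12-23m", "24-59m")

#' Causes of death by age period
#'
#' Neonatal causes act only in the 0m band; post-neonatal causes act in the
#' four bands covering 1-59 months. The residual cause `"other"` absorbs the
#' remainder of the cause-of-death distribution in every band so that cause
#' fractions always sum to one; it can never be targeted by an intervention.
#' AIDS is carried in the enumeration for completeness of published
#' cause-of-death profiles but is flagged inactive: its mortality is driven
#' by adult HIV prevalence and is modelled elsewhere.
#'
#' @return A data frame with columns `cause`, `period` (`"neonatal"` or
#'   `"postneonatal"`), `is_residual` and `active`.
#' @export
causes_table <- function() {
  neo <- c("birth asphyxia", "prematurity", "sepsis/pneumonia",
           "congenital anomalies", "tetanus", "diarrhoea", "other")
  post <- c("diarrhoea", "pneumonia", "meningitis", "measles", "malaria",
            "pertussis", "injury", "AIDS", "other")
  data.frame(
    cause = c(neo, post),
    period = c(rep("neonatal", length(neo)), rep("postneonatal", length(post))),
    is_residual = c(neo, post) == "other",
    active = c(neo, post) != "AIDS",
    stringsAsFactors = FALSE
  )
}

#' Timing tiers governing attribution order
#'
#' Interventions are credited with deaths averted in the order in which they
#' act on a child's life course: peri-conceptual interventions first, then
#' pregnancy, childbirth, vaccines, preventive-after-birth and finally
#' curative-after-birth interventions.
#'
#' @return Character vector of the six tiers in rank order.
#' @export
timing_tiers <- function() {
  c("peri-conceptual", "pregnancy", "childbirth", "vaccines",
    "preventive-after-birth", "curative-after-birth")
}

tier_rank <- function(tier) {
  r <- match(tier, timing_tiers())
  if (anyNA(r)) stop("unknown timing tier: ", paste(tier[is.na(r)], collapse = ", "))
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_prop <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

#' Construct an intervention specification
#'
#' @param id Unique identifier string.
#' @param tier One of [timing_tiers()].
#' @param effects Data frame with columns `cause`, `age_band`,
#'   `effectiveness`, `affected_fraction` and optionally logical `herd`
#'   marking cause/band cells that receive the herd adjustment. May be `NULL`
#'   for interventions acting only on risk factors.
#' @param herd_curve Optional [herd_curve()] describing herd protection.
#' @param risk_factor_effects Optional list of effects on intermediate
#'   outcomes. Each element is a list with a `factor` field (one of
#'   `"stunting"`, `"stunting_feeding"`, `"iugr"`, `"diarrhoea_incidence"`,
#'   `"wasting"`, `"breastfeeding"`) plus either `odds_ratio` (odds of the
#'   adverse outcome for uncovered versus covered children) or
#'   `effectiveness`/`affected_fraction` for prevalence-reduction routes, or
#'   `destination_split` for supplemental feeding.
#' @return An object of class `intervention`.
#' @export
intervention <- function(id, tier, effects = NULL, herd_curve = NULL,
                         risk_factor_effects = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  tier_rank(tier)
  if (!is.null(effects)) {
    stopifnot(is.data.frame(effects),
              all(c("cause", "age_band", "effectiveness", "affected_fraction")
                  %in% names(effects)))
    if (is.null(effects$herd)) effects$herd <- FALSE
  }
  structure(list(id = id, tier = tier, effects = effects,
                 herd_curve = herd_curve,
                 risk_factor_effects = risk_factor_effects),
            class = "intervention")
}

#' Assemble a scenario bundle
#'
#' A scenario bundles everything needed for a projection: baseline mortality,
#' intervention definitions, coverage trajectories, risk-factor baselines and
#' relative-risk tables. All proportions are decimals in `[0, 1]`; percent
#' appears only at I/O boundaries.
#'
#' @param name Scenario label.
#' @param baseline_year,final_year Integer years delimiting the projection.
#' @param births Named numeric vector of annual births (names are years).
#'   A single unnamed value is recycled over all years.
#' @param mortality Named list per age band, each element a list with `risk`
#'   (probability of dying in the band for a child entering it) and
#'   `cause_fractions` (named vector summing to one; `"other"` is residual).
#' @param interventions List of [intervention()] objects.
#' @param coverage Data frame with columns `intervention`, `year`, `coverage`.
#' @param risk_factors Optional list of intermediate-outcome baselines; see
#'   the package vignette for the block structure.
#' @param relative_risks Optional data frame with columns `factor`,
#'   `category`, `cause`, `age_band`, `rr` giving mortality relative risks
#'   for risk-factor categories (reference category rr = 1).
#' @return An object of class `impact_scenario`.
#' @export
scenario <- function(name, baseline_year, final_year, births, mortality,
                     interventions, coverage, risk_factors = NULL,
                     relative_risks = NULL) {
  years <- seq.int(baseline_year, final_year)
  if (is.null(names(births))) {
    stopifnot(length(births) == 1L || length(births) == length(years))
    births <- stats::setNames(rep_len(births, length(years)), years)
  }
  structure(list(
    name = name,
    baseline_year = as.integer(baseline_year),
    final_year = as.integer(final_year),
    births = births,
    mortality = mortality,
    interventions = interventions,
    coverage = coverage,
    risk_factors = risk_factors,
    relative_risks = relative_risks
  ), class = "impact_scenario")
}

#' @export
print.impact_scenario <- function(x, ...) {
  cat("<impact_scenario> ", x$name, "\n",
      "  years: ", x$baseline_year, "-", x$final_year, "\n",
      "  interventions: ", length(x$interventions), "\n", sep = "")
  invisible(x)
}

coverage_at <- function(sc, id, year) {
  rows <- sc$coverage$intervention == id & sc$coverage$year == year
  if (!any(rows)) {
    stop("coverage trajectory for '", id, "' is missing year ", year)
  }
  sc$coverage$coverage[rows][1]
}

#' Validate a scenario bundle
#'
#' Checks every structural invariant of a scenario and returns diagnostics
#' instead of raising conditions: coverage and effectiveness proportions in
#' `[0, 1]`, a baseline-year entry in each trajectory, cause fractions
#' summing to one per band (within 1e-9), mortality risks in `[0, 1]`, no
#' intervention targeting the residual cause, positive odds ratios and valid
#' herd curves. Repeated calls on the same scenario give identical output.
#'
#' @param sc An `impact_scenario`.
#' @return Character vector of diagnostics; empty when the scenario is valid.
#' @export
validate_scenario <- function(sc) {
  d <- character(0)
  say <- function(...) d[[length(d) + 1L]] <<- paste0(...)

  bands <- band_labels()
  if (!setequal(names(sc$mortality), bands)) {
    say("mortality: age bands must be exactly {", paste(bands, collapse = ", "), "}")
  }
  for (b in intersect(names(sc$mortality), bands)) {
    m <- sc$mortality[[b]]
    if (!is_prop(m$risk)) say("mortality[", b, "]$risk: not a proportion in [0,1]")
    cf <- m$cause_fractions
    if (is.null(cf) || !is.numeric(cf) || is.null(names(cf))) {
      say("mortality[", b, "]$cause_fractions: missing or unnamed")
    } else {
      if (any(cf < 0)) say("mortality[", b, "]$cause_fractions: negative fraction")
      if (abs(sum(cf) - 1) > 1e-9) {
        say("mortality[", b, "]$cause_fractions: sum to ",
            format(sum(cf)), ", not 1")
      }
      period <- if (b == NEONATAL_BAND) "neonatal" else "postneonatal"
      known <- causes_table()$cause[causes_table()$period == period]
      bad <- setdiff(names(cf), known)
      if (length(bad)) {
        say("mortality[", b, "]$cause_fractions: unknown cause(s) ",
            paste(bad, collapse = ", "))
      }
    }
  }

  ids <- vapply(sc$interventions, function(iv) iv$id, "")
  if (anyDuplicated(ids)) say("interventions: duplicated id(s)")
  for (iv in sc$interventions) {
    ef <- iv$effects
    if (!is.null(ef)) {
      if (!is_prop(ef$effectiveness)) {
        say("intervention[", iv$id, "]: effectiveness outside [0,1]")
      }
      if (!is_prop(ef$affected_fraction)) {
        say("intervention[", iv$id, "]: affected_fraction outside [0,1]")
      }
      if (any(ef$cause == "other")) {
        say("intervention[", iv$id, "]: targets the residual cause")
      }
      if (any(ef$cause == "AIDS")) {
        say("intervention[", iv$id, "]: targets an inactive cause (AIDS)")
      }
      bad <- setdiff(ef$age_band, bands)
      if (length(bad)) {
        say("intervention[", iv$id, "]: unknown age band(s) ",
            paste(bad, collapse = ", "))
      }
    }
    hc <- iv$herd_curve
    if (!is.null(hc)) {
      ok <- is_prop(c(hc$lower, hc$upper, hc$max_effect)) && hc$lower < hc$upper
      if (!ok) say("intervention[", iv$id, "]: invalid herd curve")
    }
    for (rf in iv$risk_factor_effects %||% list()) {
      ors <- c(rf[["odds_ratio"]], rf[["odds_ratios"]])
      if (!is.null(ors) && (!is.numeric(ors) || any(ors <= 0))) {
        say("intervention[", iv$id, "]: non-positive odds ratio for ",
            rf$factor)
      }
    }
  }

  cov <- sc$coverage
  if (!is_prop(cov$coverage)) {
    bad <- unique(cov$intervention[!(cov$coverage >= 0 & cov$coverage <= 1)])
    say("coverage: values outside [0,1] for ", paste(bad, collapse = ", "))
  }
  for (id in unique(cov$intervention)) {
    yrs <- cov$year[cov$intervention == id]
    if (!(sc$baseline_year %in% yrs)) {
      say("coverage[", id, "]: baseline year ", sc$baseline_year, " absent")
    }
  }
  orphan <- setdiff(unique(cov$intervention), ids)
  if (length(orphan)) {
    say("coverage: trajectories for undefined intervention(s) ",
        paste(orphan, collapse = ", "))
  }

  rf <- sc$risk_factors
  if (!is.null(rf)) {
    for (nm in c("stunting", "severe_wasting")) {
      p <- rf[[nm]]$prevalence
      if (!is.null(p) && !(is.numeric(p) && all(p > 0 & p < 1))) {
        say("risk_factors$", nm, "$prevalence: values must lie in (0,1)")
      }
    }
    bf <- rf$breastfeeding
    if (!is.null(bf)) {
      for (b in names(bf$fractions)) {
        f <- bf$fractions[[b]]
        if (abs(sum(f) - 1) > 1e-9) {
          say("risk_factors$breastfeeding$fractions[", b, "]: sum to ",
              format(sum(f)), ", not 1")
        }
      }
    }
  }
  d
}

# ---- serialization ----------------------------------------------------------

# named atomic vectors must become JSON objects, not arrays
listify_named <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, listify_named))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

scenario_to_list <- function(sc) {
  list(
    name = sc$name,
    baseline_year = sc$baseline_year,
    final_year = sc$final_year,
    births = as.list(sc$births),
    mortality = lapply(sc$mortality, function(m) {
      list(risk = m$risk, cause_fractions = as.list(m$cause_fractions))
    }),
    interventions = stats::setNames(lapply(sc$interventions, function(iv) {
      out <- list(id = iv$id, tier = iv$tier)
      if (!is.null(iv$effects)) out$effects <- iv$effects
      if (!is.null(iv$herd_curve)) {
        out$herd_curve <- list(lower = iv$herd_curve$lower,
                               upper = iv$herd_curve$upper,
                               max = iv$herd_curve$max_effect)
      }
      if (!is.null(iv$risk_factor_effects)) {
        out$risk_factor_effects <- stats::setNames(
          listify_named(iv$risk_factor_effects),
          vapply(iv$risk_factor_effects, function(e) e$factor, "")
        )
      }
      out
    }), vapply(sc$interventions, function(iv) iv$id, "")),
    coverage = sc$coverage,
    risk_factors = listify_named(sc$risk_factors %||% list()),
    relative_risks = sc$relative_risks
  )
}

list_to_scenario <- function(x) {
  rf <- x$risk_factors
  if (length(rf) == 0) rf <- NULL
  if (!is.null(rf)) {
    for (nm in c("stunting", "severe_wasting", "diarrhoea")) {
      for (fld in c("prevalence", "episodes")) {
        if (!is.null(rf[[nm]][[fld]])) rf[[nm]][[fld]] <- unlist(rf[[nm]][[fld]])
      }
    }
    if (!is.null(rf$breastfeeding$fractions)) {
      rf$breastfeeding$fractions <- lapply(rf$breastfeeding$fractions, unlist)
    }
    if (!is.null(rf$stunting$feeding)) {
      rf$stunting$feeding <- lapply(rf$stunting$feeding, unlist)
    }
  }
  scenario(
    name = x$name,
    baseline_year = x$baseline_year,
    final_year = x$final_year,
    births = unlist(x$births),
    mortality = lapply(x$mortality, function(m) {
      list(risk = m$risk, cause_fractions = unlist(m$cause_fractions))
    }),
    interventions = lapply(x$interventions, function(iv) {
      hc <- NULL
      if (!is.null(iv$herd_curve)) {
        hc <- herd_curve(iv$herd_curve$lower, iv$herd_curve$upper,
                         iv$herd_curve$max)
      }
      rfe <- iv$risk_factor_effects
      if (!is.null(rfe)) {
        rfe <- lapply(rfe, function(e) {
          if (!is.null(e$destination_split)) {
            e$destination_split <- unlist(e$destination_split)
          }
          e
        })
      }
      intervention(iv$id, iv$tier, effects = iv$effects, herd_curve = hc,
                   risk_factor_effects = rfe)
    }),
    coverage = x$coverage,
    risk_factors = rf,
    relative_risks = x$relative_risks
  )
}

#' Read and write scenario bundles as JSON
#'
#' A scenario is stored as a single JSON document with all proportions as
#' decimals. `write_scenario()` followed by `read_scenario()` round-trips the
#' scenario content exactly.
#'
#' @param sc An `impact_scenario`.
#' @param path File path of the JSON document.
#' @return `read_scenario()` returns an `impact_scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(sc, path) {
  jsonlite::write_json(scenario_to_list(sc), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  list_to_scenario(jsonlite::read_json(path, simplifyVector = TRUE,
                                       simplifyMatrix = FALSE))
}
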