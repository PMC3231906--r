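# Calendar occupancy of the five age bands for a cohort born in year tb.
# The first three bands fall in the year of birth; 12-23m in the next year;
# 24-59m is spread uniformly over the following three years.
band_schedule <- function(tb) {
  data.frame(
    age_band = c("0m", "1-5m", "6-11m", "12-23m",
                 "24-59m", "24-59m", "24-59m"),
    year = c(tb, tb, tb, tb + 1L, tb + 2L, tb + 3L, tb + 4L),
    frac = c(1, 1, 1, 1, 1 / 3, 1 / 3, 1 / 3),
    stringsAsFactors = FALSE
  )
}

reduction_lookup <- function(combined) {
  if (is.null(combined) || nrow(combined) == 0) {
    return(function(cause, band, year) 0)
  }
  key <- paste(combined$year, combined$age_band, combined$cause, sep = "\r")
  vals <- stats::setNames(combined$reduction, key)
  function(cause, band, year) {
    v <- vals[paste(year, band, cause, sep = "\r")]
    if (is.na(v)) 0 else unname(v)
  }
}

# Walk one birth cohort through its band schedule, returning death rows and
# entrant counts for calendar years inside [from, to].
walk_cohort <- function(sc, tb, births, lookup, from, to) {
  bands <- band_labels()
  alive <- births
  deaths <- list()
  entrants <- list()
  sched <- band_schedule(tb)
  prev_band <- ""
  for (k in seq_len(nrow(sched))) {
    b <- sched$age_band[k]
    yr <- sched$year[k]
    if (yr > to) break
    m <- sc$mortality[[b]]
    cf <- m$cause_fractions
    if (b != prev_band && yr >= from) {
      entrants[[length(entrants) + 1L]] <- data.frame(
        year = yr, age_band = b, entrants = alive, stringsAsFactors = FALSE)
    }
    prev_band <- b
    risk_slice <- m$risk * sched$frac[k] * cf
    red <- vapply(names(cf), function(cs) lookup(cs, b, yr), numeric(1))
    d <- alive * risk_slice * (1 - red)
    if (yr >= from) {
      deaths[[length(deaths) + 1L]] <- data.frame(
        year = yr, age_band = b, cause = names(cf), deaths = unname(d),
        stringsAsFactors = FALSE)
    }
    alive <- alive - sum(d)
  }
  list(deaths = deaths, entrants = entrants)
}

run_engine <- function(sc, lookup) {
  from <- sc$baseline_year
  to <- sc$final_year
  births_of <- function(tb) {
    nm <- as.character(max(tb, from))  # pre-baseline cohorts at baseline size
    unname(sc$births[[nm]])
  }
  deaths <- list()
  entrants <- list()
  # cohorts born up to four years before baseline still occupy the 24-59m
  # band inside the projection window
  for (tb in seq.int(from - 4L, to)) {
    w <- walk_cohort(sc, tb, births_of(tb), lookup, from, to)
    deaths <- c(deaths, w$deaths)
    entrants <- c(entrants, w$entrants)
  }
  d <- do.call(rbind, deaths)
  d <- stats::aggregate(deaths ~ year + age_band + cause, data = d, FUN = sum)
  e <- do.call(rbind, entrants)
  e <- stats::aggregate(entrants ~ year + age_band, data = e, FUN = sum)
  list(deaths = d, entrants = e)
}

#' Project deaths and deaths averted through the cohort engine
#'
#' A simplified cohort-component engine carries annual birth cohorts through
#' the five age bands: the three infant bands are lived in the year of
#' birth, the 12-23m band in the following year and the 24-59m band spread
#' uniformly over the three years after that. The engine is run twice — once
#' at baseline coverage (all reductions zero) and once with the scenario's
#' combined cause-specific reductions — and deaths averted are the
#' difference. Survivors spill over: children saved in one band enter the
#' next band, so a neonatal-only reduction increases the entrants of the
#' 1-5m band by exactly the neonatal deaths averted. Deaths averted are
#' attributed to interventions by [attribute_shares()] within each
#' (cause, band, year) cell, with the shares of intermediate-outcome
#' pseudo-interventions re-split over the interventions that moved the risk
#' factor, and summed per intervention across causes.
#'
#' Years before the baseline are warmed up with baseline-year births and
#' baseline mortality so that the ledger is complete (and stationary under
#' flat coverage) from the first projection year.
#'
#' @param sc A validated `impact_scenario`.
#' @param reductions An `impact_reductions` object from
#'   [compute_reductions()]; computed on the fly when omitted.
#' @return List of class `cohort_ledger` with data frames `deaths`
#'   (year, age_band, cause, baseline deaths, scenario deaths, averted),
#'   `entrants`, `averted_by_intervention` (year, intervention, averted),
#'   `averted_detail` (per cause and band) and `band_risks` (effective
#'   all-cause band risks per year).
#' @export
project_cohort <- function(sc, reductions = NULL) {
  diags <- validate_scenario(sc)
  if (length(diags)) {
    stop("scenario is invalid:\n", paste(" -", diags, collapse = "\n"))
  }
  if (is.null(reductions)) reductions <- compute_reductions(sc)
  lookup <- reduction_lookup(reductions$combined)

  baseline <- run_engine(sc, function(cause, band, year) 0)
  scen <- run_engine(sc, lookup)

  d <- merge(baseline$deaths, scen$deaths,
             by = c("year", "age_band", "cause"),
             suffixes = c("_baseline", ""))
  d$averted <- d$deaths_baseline - d$deaths
  d <- d[order(d$year, d$age_band, d$cause), , drop = FALSE]

  e <- merge(baseline$entrants, scen$entrants, by = c("year", "age_band"),
             suffixes = c("_baseline", ""))

  ## attribute deaths averted to interventions
  pe <- reductions$per_entity
  pw <- reductions$pseudo_weights
  det <- list()
  cells <- d[d$averted != 0, c("year", "age_band", "cause", "averted")]
  for (k in seq_len(nrow(cells))) {
    cl <- cells[k, ]
    rows <- pe[pe$year == cl$year & pe$age_band == cl$age_band &
                 pe$cause == cl$cause, , drop = FALSE]
    if (!nrow(rows)) next
    shares <- attribute_shares(
      stats::setNames(rows$reduction, rows$entity),
      stats::setNames(rows$tier, rows$entity))
    for (ent in names(shares)) {
      if (shares[[ent]] == 0) next
      if (!is.null(pw) && ent %in% pw$factor) {
        wr <- pw[pw$year == cl$year & pw$age_band == cl$age_band &
                   pw$factor == ent, , drop = FALSE]
        if (nrow(wr)) {
          for (j in seq_len(nrow(wr))) {
            det[[length(det) + 1L]] <- data.frame(
              year = cl$year, intervention = wr$source[j],
              cause = cl$cause, age_band = cl$age_band,
              averted = cl$averted * shares[[ent]] * wr$weight[j],
              stringsAsFactors = FALSE)
          }
          next
        }
      }
      det[[length(det) + 1L]] <- data.frame(
        year = cl$year, intervention = ent, cause = cl$cause,
        age_band = cl$age_band, averted = cl$averted * shares[[ent]],
        stringsAsFactors = FALSE)
    }
  }
  averted_detail <- if (length(det)) do.call(rbind, det) else data.frame(
    year = integer(0), intervention = character(0), cause = character(0),
    age_band = character(0), averted = numeric(0), stringsAsFactors = FALSE)
  averted_by_iv <- if (nrow(averted_detail)) {
    stats::aggregate(averted ~ year + intervention, data = averted_detail,
                     FUN = sum)
  } else {
    data.frame(year = integer(0), intervention = character(0),
               averted = numeric(0), stringsAsFactors = FALSE)
  }

  ## effective all-cause band risks per year (for rate summaries)
  br <- list()
  for (t in seq.int(sc$baseline_year, sc$final_year)) {
    for (b in band_labels()) {
      m <- sc$mortality[[b]]
      red <- vapply(names(m$cause_fractions),
                    function(cs) lookup(cs, b, t), numeric(1))
      acr <- all_cause_reduction(
        stats::setNames(red, names(m$cause_fractions)), m$cause_fractions)
      br[[length(br) + 1L]] <- data.frame(
        year = t, age_band = b, risk_baseline = m$risk,
        risk = m$risk * (1 - acr), stringsAsFactors = FALSE)
    }
  }

  structure(list(
    deaths = d,
    entrants = e,
    averted_by_intervention = averted_by_iv,
    averted_detail = averted_detail,
    band_risks = do.call(rbind, br)
  ), class = "cohort_ledger")
}

#' Summarise mortality rates per projection year
#'
#' Computes synthetic-cohort mortality rates from the effective band risks
#' of each year: the neonatal rate is the 0m band risk, the infant rate is
#' the cumulative death risk over the first three bands,
#' \eqn{1 - \prod_b (1 - q_b)}, and the under-five rate extends the product
#' over all five bands. All rates are per 1000 live births.
#'
#' @param ledger A `cohort_ledger` from [project_cohort()].
#' @return Data frame with columns `year`, `nmr`, `imr`, `u5mr` and their
#'   `_baseline` counterparts.
#' @export
summarize_rates <- function(ledger) {
  br <- ledger$band_risks
  out <- list()
  for (t in sort(unique(br$year))) {
    q <- stats::setNames(br$risk[br$year == t], br$age_band[br$year == t])
    q0 <- stats::setNames(br$risk_baseline[br$year == t],
                          br$age_band[br$year == t])
    cum <- function(qv, bs) (1 - prod(1 - qv[bs])) * 1000
    infant <- c("0m", "1-5m", "6-11m")
    out[[length(out) + 1L]] <- data.frame(
      year = t,
      nmr = cum(q, "0m"), imr = cum(q, infant), u5mr = cum(q, band_labels()),
      nmr_baseline = cum(q0, "0m"), imr_baseline = cum(q0, infant),
      u5mr_baseline = cum(q0, band_labels()), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
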