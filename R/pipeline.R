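# Intermediate-outcome pseudo-interventions act preventively in the
# attribution ordering; their credited share is re-split over the real
# interventions that moved the risk factor.
PSEUDO_TIER <- "preventive-after-birth"

rf_effects <- function(sc, factor) {
  out <- list()
  for (iv in sc$interventions) {
    for (e in iv$risk_factor_effects %||% list()) {
      if (identical(e$factor, factor)) {
        e$id <- iv$id
        out[[length(out) + 1L]] <- e
      }
    }
  }
  out
}

rr_vector <- function(sc, factor, band, cause) {
  rr <- sc$relative_risks
  rows <- rr$factor == factor & rr$age_band == band & rr$cause == cause
  stats::setNames(rr$rr[rows], rr$category[rows])
}

rr_causes <- function(sc, factor, band) {
  rr <- sc$relative_risks
  if (is.null(rr)) return(character(0))
  unique(rr$cause[rr$factor == factor & rr$age_band == band])
}

normalize_weights <- function(w) {
  w <- w[w > 0]
  if (length(w) == 0) return(w)
  w / sum(w)
}

#' Compute per-year mortality reductions for a scenario
#'
#' Runs the full effect calculus for every projection year after the
#' baseline: direct effects with herd adjustment, IUGR and diarrhoea
#' incidence scale-downs, the stunting cohort progression across age bands,
#' supplemental feeding's redistribution of severely wasted children, and
#' breastfeeding category shifts. Intermediate outcomes enter mortality as
#' pseudo-interventions (`"stunting"`, `"wasting"`, `"iugr"`,
#' `"breastfeeding"`) whose cause-specific reductions come from changes in
#' the occupancy-weighted average relative risk; their attribution weight is
#' traced back to the real interventions that moved the risk factor.
#'
#' @param sc A validated `impact_scenario`.
#' @return List of class `impact_reductions` with elements
#'   `per_entity` (year, entity, tier, cause, age_band, reduction),
#'   `combined` (year, age_band, cause, reduction),
#'   `trajectories` (nutrition indicators per year and band) and
#'   `pseudo_weights` (year, age_band, factor, source, weight).
#' @export
compute_reductions <- function(sc) {
  base <- sc$baseline_year
  years <- seq.int(base + 1L, sc$final_year)
  bands <- band_labels()
  st_cfg <- sc$risk_factors$stunting
  ct <- causes_table()

  ent <- list()   # per-entity reduction rows
  wts <- list()   # pseudo attribution weight rows
  trj <- list()   # nutrition trajectories
  add_ent <- function(year, entity, tier, cause, band, r) {
    ent[[length(ent) + 1L]] <<- data.frame(
      year = year, entity = entity, tier = tier, cause = cause,
      age_band = band, reduction = r, stringsAsFactors = FALSE)
  }
  add_wt <- function(year, band, factor, w) {
    if (length(w) == 0) return(invisible())
    wts[[length(wts) + 1L]] <<- data.frame(
      year = year, age_band = band, factor = factor,
      source = names(w), weight = unname(w), stringsAsFactors = FALSE)
  }

  iugr0 <- sc$risk_factors$iugr$fraction
  eps0 <- sc$risk_factors$diarrhoea$episodes
  stunt0 <- st_cfg$prevalence
  wast0 <- sc$risk_factors$severe_wasting$prevalence
  bf_cfg <- sc$risk_factors$breastfeeding

  # baseline-year nutrition row
  for (b in bands) {
    trj[[length(trj) + 1L]] <- data.frame(
      year = base, age_band = b,
      stunting = if (!is.null(stunt0)) stunt0[[b]] else NA_real_,
      severe_wasting = if (!is.null(wast0)) wast0[[b]] else NA_real_,
      diarrhoea_episodes = if (!is.null(eps0) && b %in% names(eps0))
        eps0[[b]] else NA_real_,
      iugr = iugr0 %||% NA_real_, stringsAsFactors = FALSE)
  }

  for (t in years) {
    ## ---- direct effects (with herd adjustment) ----
    for (iv in sc$interventions) {
      if (is.null(iv$effects)) next
      c0 <- coverage_at(sc, iv$id, base)
      ctv <- coverage_at(sc, iv$id, t)
      for (k in seq_len(nrow(iv$effects))) {
        e <- iv$effects[k, ]
        r <- single_reduction(e$effectiveness, e$affected_fraction, c0, ctv)
        if (isTRUE(e$herd) && !is.null(iv$herd_curve)) {
          h <- incremental_herd(iv$herd_curve, c0, ctv)
          if (h > 0) r <- total_with_herd(r, h)
        }
        add_ent(t, iv$id, iv$tier, e$cause, e$age_band, r)
      }
    }

    ## ---- IUGR scale-down ----
    iugr_t <- iugr0
    iugr_w <- numeric(0)
    if (!is.null(iugr0)) {
      evs <- rf_effects(sc, "iugr")
      if (length(evs)) {
        rs <- vapply(evs, function(e) {
          single_reduction(e$effectiveness, e$affected_fraction %||% 1,
                           coverage_at(sc, e$id, base),
                           coverage_at(sc, e$id, t))
        }, numeric(1))
        names(rs) <- vapply(evs, function(e) e$id, "")
        iugr_t <- iugr0 * (1 - combine_reductions(rs))
        iugr_w <- normalize_weights(rs)
      }
      if (length(rr_causes(sc, "iugr", NEONATAL_BAND)) && iugr_t != iugr0) {
        occ0 <- c(iugr = iugr0, normal = 1 - iugr0)
        occt <- c(iugr = iugr_t, normal = 1 - iugr_t)
        for (cs in rr_causes(sc, "iugr", NEONATAL_BAND)) {
          rr <- rr_vector(sc, "iugr", NEONATAL_BAND, cs)
          r <- mortality_reduction_from_arr(average_relative_risk(occt, rr),
                                            average_relative_risk(occ0, rr))
          add_ent(t, "iugr", PSEUDO_TIER, cs, NEONATAL_BAND, r)
        }
        add_wt(t, NEONATAL_BAND, "iugr", iugr_w)
      }
    }

    ## ---- diarrhoea incidence scale-down ----
    eps_t <- eps0
    eps_w <- numeric(0)
    if (!is.null(eps0)) {
      evs <- rf_effects(sc, "diarrhoea_incidence")
      if (length(evs)) {
        rs <- vapply(evs, function(e) {
          single_reduction(e$effectiveness, e$affected_fraction %||% 1,
                           coverage_at(sc, e$id, base),
                           coverage_at(sc, e$id, t))
        }, numeric(1))
        names(rs) <- vapply(evs, function(e) e$id, "")
        eps_t <- eps0 * (1 - combine_reductions(rs))
        eps_w <- normalize_weights(rs)
      }
    }

    ## ---- stunting cohort progression across bands ----
    stunt_t <- stunt0
    carry_w <- normalize_weights(iugr_w)  # sources behind the 0m carry-over
    if (!is.null(stunt0)) {
      for (b in bands) {
        p0 <- stunt0[[b]]
        dets <- list()
        det_src <- list()  # per determinant: weights over real interventions

        # carried risk factor: IUGR for neonates, previous-band stunting after
        if (b == NEONATAL_BAND) {
          if (!is.null(iugr0) && !is.null(st_cfg$iugr_odds_ratio) &&
              iugr_t != iugr0) {
            dets[[length(dets) + 1L]] <- list(
              source = ".carry", odds_ratio = st_cfg$iugr_odds_ratio,
              baseline_risky_fraction = iugr0,
              target_risky_fraction = iugr_t)
            det_src[[length(dets)]] <- carry_w
          }
        } else {
          pb <- bands[match(b, bands) - 1L]
          if (!is.null(st_cfg$carryover_odds_ratio) &&
              stunt_t[[pb]] != stunt0[[pb]]) {
            dets[[length(dets) + 1L]] <- list(
              source = ".carry", odds_ratio = st_cfg$carryover_odds_ratio,
              baseline_risky_fraction = stunt0[[pb]],
              target_risky_fraction = stunt_t[[pb]])
            det_src[[length(dets)]] <- carry_w
          }
        }

        # zinc-style supplementation determinants (two-state odds ratio)
        for (e in rf_effects(sc, "stunting")) {
          bds <- e$age_bands %||% bands
          if (!(b %in% bds)) next
          dets[[length(dets) + 1L]] <- list(
            source = e$id, odds_ratio = e$odds_ratio,
            baseline_risky_fraction = 1 - coverage_at(sc, e$id, base),
            target_risky_fraction = 1 - coverage_at(sc, e$id, t))
          det_src[[length(dets)]] <- stats::setNames(1, e$id)
        }

        # complementary feeding (four-state solve over food security x reach)
        for (e in rf_effects(sc, "stunting_feeding")) {
          bds <- e$age_bands %||% POSTNEONATAL_BANDS
          if (!(b %in% bds)) next
          q <- st_cfg$food_secure_fraction
          c0 <- coverage_at(sc, e$id, base)
          cv <- coverage_at(sc, e$id, t)
          if (cv == c0) next
          f0 <- c(q * c0, q * (1 - c0), (1 - q) * c0, (1 - q) * (1 - c0))
          p4 <- solve_four_state(e$odds_ratios, f0, p0)
          ft <- c(q * cv, q * (1 - cv), (1 - q) * cv, (1 - q) * (1 - cv))
          dets[[length(dets) + 1L]] <- list(
            source = e$id,
            reduction = prevalence_reduction(p0, sum(ft * p4)))
          det_src[[length(dets)]] <- stats::setNames(1, e$id)
        }

        # diarrhoea episodes determinant (population OR = per-episode OR^i)
        if (!is.null(eps0) && b %in% names(eps0) &&
            !is.null(st_cfg$diarrhoea_odds_ratio_per_episode) &&
            eps0[[b]] > 0 && eps_t[[b]] < eps0[[b]]) {
          m <- diarrhoea_or_to_two_state(
            eps0[[b]], eps_t[[b]], st_cfg$diarrhoea_odds_ratio_per_episode)
          dets[[length(dets) + 1L]] <- list(
            source = ".diarrhoea", odds_ratio = m$odds_ratio,
            baseline_risky_fraction = m$risky_fraction_baseline,
            target_risky_fraction = m$risky_fraction_target)
          det_src[[length(dets)]] <- eps_w
        }

        upd <- update_stunting_cohort(p0, dets)
        stunt_t[[b]] <- upd$stunting

        # attribution weights for this band's stunting change
        w <- numeric(0)
        for (k in seq_along(dets)) {
          rk <- max(upd$reductions[[k]], 0)
          srcs <- det_src[[k]]
          for (s in names(srcs)) {
            w[s] <- (if (s %in% names(w)) w[[s]] else 0) + rk * srcs[[s]]
          }
        }
        w <- normalize_weights(w)
        if (abs(stunt_t[[b]] - p0) > 1e-12) {
          occ0 <- prevalence_to_bands(p0)
          occt <- prevalence_to_bands(stunt_t[[b]])
          for (cs in rr_causes(sc, "stunting", b)) {
            rr <- rr_vector(sc, "stunting", b, cs)
            r <- mortality_reduction_from_arr(
              average_relative_risk(occt, rr),
              average_relative_risk(occ0, rr))
            add_ent(t, "stunting", PSEUDO_TIER, cs, b, r)
          }
          add_wt(t, b, "stunting", w)
        }
        carry_w <- w  # sources carried into the next band
      }
    }

    ## ---- wasting: supplemental feeding ----
    wast_t <- wast0
    if (!is.null(wast0)) {
      for (e in rf_effects(sc, "wasting")) {
        dc <- coverage_at(sc, e$id, t) - coverage_at(sc, e$id, base)
        if (dc <= 0) next
        for (b in intersect(names(wast0), bands)) {
          occ0 <- prevalence_to_bands(wast0[[b]], cut = -3)
          occt <- apply_supplemental_feeding(occ0, dc, e$destination_split)
          wast_t[[b]] <- occt[["below_m3"]]
          for (cs in rr_causes(sc, "wasting", b)) {
            rr <- rr_vector(sc, "wasting", b, cs)
            r <- mortality_reduction_from_arr(
              average_relative_risk(occt, rr),
              average_relative_risk(occ0, rr))
            add_ent(t, "wasting", PSEUDO_TIER, cs, b, r)
          }
          add_wt(t, b, "wasting", stats::setNames(1, e$id))
        }
      }
    }

    ## ---- breastfeeding promotion ----
    if (!is.null(bf_cfg)) {
      for (e in rf_effects(sc, "breastfeeding")) {
        c0 <- coverage_at(sc, e$id, base)
        cv <- coverage_at(sc, e$id, t)
        if (cv == c0) next
        for (b in names(bf_cfg$fractions)) {
          f0 <- bf_cfg$fractions[[b]]
          imp <- bf_cfg$improved[[b]] %||% "exclusive"
          ftv <- update_breastfeeding(f0, e$odds_ratio, c0, cv, improved = imp)
          for (cs in rr_causes(sc, "breastfeeding", b)) {
            rr <- rr_vector(sc, "breastfeeding", b, cs)
            r <- mortality_reduction_from_arr(
              average_relative_risk(ftv, rr),
              average_relative_risk(f0, rr))
            add_ent(t, "breastfeeding", PSEUDO_TIER, cs, b, r)
          }
          add_wt(t, b, "breastfeeding", stats::setNames(1, e$id))
        }
      }
    }

    for (b in bands) {
      trj[[length(trj) + 1L]] <- data.frame(
        year = t, age_band = b,
        stunting = if (!is.null(stunt_t)) stunt_t[[b]] else NA_real_,
        severe_wasting = if (!is.null(wast_t)) wast_t[[b]] else NA_real_,
        diarrhoea_episodes = if (!is.null(eps_t) && b %in% names(eps_t))
          eps_t[[b]] else NA_real_,
        iugr = iugr_t %||% NA_real_, stringsAsFactors = FALSE)
    }
  }

  per_entity <- if (length(ent)) do.call(rbind, ent) else data.frame(
    year = integer(0), entity = character(0), tier = character(0),
    cause = character(0), age_band = character(0), reduction = numeric(0),
    stringsAsFactors = FALSE)

  # drop reductions for inactive causes (AIDS) and the residual cause
  keep <- !(per_entity$cause %in% ct$cause[!ct$active | ct$is_residual])
  per_entity <- per_entity[keep, , drop = FALSE]

  combined <- if (nrow(per_entity)) {
    agg <- stats::aggregate(
      reduction ~ year + age_band + cause, data = per_entity,
      FUN = combine_reductions)
    agg[order(agg$year, agg$age_band, agg$cause), , drop = FALSE]
  } else {
    data.frame(year = integer(0), age_band = character(0),
               cause = character(0), reduction = numeric(0),
               stringsAsFactors = FALSE)
  }

  structure(list(
    per_entity = per_entity,
    combined = combined,
    trajectories = do.call(rbind, trj),
    pseudo_weights = if (length(wts)) do.call(rbind, wts) else NULL
  ), class = "impact_reductions")
}
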