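#' Solve a two-status odds-ratio prevalence decomposition
#'
#' A population with overall prevalence `P` of an adverse outcome (e.g.
#' stunting) is split into a risky status (fraction `F_k`, e.g. children not
#' receiving zinc supplementation) and a non-risky status (fraction
#' `1 - F_k`). The status-specific prevalences `P_k`, `P_1` satisfy the
#' odds-ratio relation
#' \deqn{P_k = \frac{OR \, P_1}{1 - P_1 + OR \, P_1}}
#' and the mixture constraint \eqn{F_k P_k + (1 - F_k) P_1 = P}. Eliminating
#' `P_k` gives a quadratic in `P_1`, solved here in closed form with the root
#' in `(0, 1)`. The odds-ratio formulation guarantees both status-specific
#' probabilities stay below 1.
#'
#' @param odds_ratio Odds of the outcome in the risky status relative to the
#'   non-risky status; must be positive.
#' @param risky_fraction Fraction of the population in the risky status.
#' @param prevalence Overall outcome prevalence, in `(0, 1)`.
#' @return List with `p_risky` and `p_nonrisky`.
#' @export
#' @examples
#' # preventive zinc: OR 1.18, 75% unsupplemented, 35% stunted overall
#' solve_two_state(1.18, 0.75, 0.35)
solve_two_state <- function(odds_ratio, risky_fraction, prevalence) {
  stopifnot(is.numeric(odds_ratio), odds_ratio > 0,
            is_prop(risky_fraction),
            is.numeric(prevalence), prevalence > 0, prevalence < 1)
  fk <- risky_fraction
  a <- (1 - fk) * (odds_ratio - 1)
  b <- fk * odds_ratio + (1 - fk) - prevalence * (odds_ratio - 1)
  cc <- -prevalence
  if (abs(a) < 1e-14) {
    p1 <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("inconsistent inputs: no real solution")
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    ok <- roots > 0 & roots < 1
    if (!any(ok)) stop("inconsistent inputs: no status-specific prevalence in (0,1)")
    p1 <- roots[ok][1]
  }
  pk <- odds_ratio * p1 / (1 - p1 + odds_ratio * p1)
  # guard against numerical drift: both defining relations must hold tightly
  stopifnot(abs(fk * pk + (1 - fk) * p1 - prevalence) < 1e-10)
  list(p_risky = pk, p_nonrisky = p1)
}

#' Project overall prevalence under a new status mix
#'
#' Holds the status-specific prevalences fixed and re-weights them by the new
#' fraction in the risky status: \eqn{P_t = F_{k,t} P_k + (1 - F_{k,t}) P_1}.
#'
#' @param p_risky,p_nonrisky Status-specific prevalences from
#'   [solve_two_state()].
#' @param risky_fraction New fraction of the population in the risky status.
#' @return Projected overall prevalence.
#' @export
project_prevalence <- function(p_risky, p_nonrisky, risky_fraction) {
  stopifnot(is_prop(p_risky), is_prop(p_nonrisky), is_prop(risky_fraction))
  risky_fraction * p_risky + (1 - risky_fraction) * p_nonrisky
}

#' Proportional decline in prevalence
#'
#' Expresses a prevalence change as the proportional decline from baseline,
#' \eqn{(P_0 - P_t) / P_0}; positive when prevalence falls.
#'
#' @param p_baseline Baseline prevalence (> 0).
#' @param p_target Projected prevalence.
#' @return Proportional decline.
#' @export
prevalence_reduction <- function(p_baseline, p_target) {
  stopifnot(is.numeric(p_baseline), is.numeric(p_target))
  if (p_baseline <= 0) stop("baseline prevalence must be positive")
  (p_baseline - p_target) / p_baseline
}

#' Solve a four-status odds-ratio prevalence decomposition
#'
#' Used for complementary feeding, where the population falls into four
#' states (food secure with promotion — the least risky reference — food
#' secure without promotion, food insecure with promotion and
#' supplementation, food insecure without either). Three odds ratios relate
#' each non-reference state to the reference. The four status-specific
#' prevalences must satisfy the three odds relations plus the four-term
#' mixture constraint; substituting the odds relations into the mixture
#' constraint leaves one equation in the reference prevalence, which is
#' strictly increasing and is solved by a bracketed root-finder. (The same
#' root solves the equivalent quartic polynomial; the bracketed form avoids
#' quartic branch selection.)
#'
#' @param odds_ratios Numeric vector of three odds ratios (> 0) for the
#'   non-reference states relative to the reference state.
#' @param fractions Numeric vector of four population fractions (reference
#'   first) summing to 1.
#' @param prevalence Overall prevalence in `(0, 1)`.
#' @return Numeric vector of four status-specific prevalences (reference
#'   first), named after `fractions` when those are named.
#' @export
solve_four_state <- function(odds_ratios, fractions, prevalence) {
  stopifnot(length(odds_ratios) == 3L, all(odds_ratios > 0),
            length(fractions) == 4L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-9,
            prevalence > 0, prevalence < 1)
  ors <- c(1, unname(odds_ratios))
  status_prev <- function(p1) ors * p1 / (1 - p1 + ors * p1)
  f <- function(p1) sum(fractions * status_prev(p1)) - prevalence
  eps <- 1e-15
  if (f(eps) > 0 || f(1 - eps) < 0) {
    stop("inconsistent inputs: no admissible reference prevalence in (0,1)")
  }
  p1 <- stats::uniroot(f, c(eps, 1 - eps), tol = 1e-15)$root
  p <- status_prev(p1)
  stopifnot(abs(sum(fractions * p) - prevalence) < 1e-10)
  stats::setNames(p, names(fractions))
}

#' Map a diarrhoea incidence change onto a two-status risk model
#'
#' Diarrhoea's effect on stunting is modelled with a per-episode odds ratio:
#' the population-average odds ratio is the single-episode odds ratio raised
#' to the mean number of episodes per year, \eqn{AO = OR^{i}}. A reduction in
#' incidence from `baseline_episodes` to `target_episodes` is represented as
#' moving children from having `baseline_episodes` cases to having none: the
#' fraction keeping the baseline incidence (the risky status) is
#' `target/baseline`, the rest have no diarrhoea.
#'
#' @param baseline_episodes Mean episodes per child-year at baseline (> 0).
#' @param target_episodes Mean episodes in the projection year
#'   (`<= baseline_episodes`).
#' @param per_episode_or Odds ratio of stunting per diarrhoea episode.
#' @return List with `odds_ratio` (population-average `OR^i`),
#'   `risky_fraction_baseline` (1: all children at the baseline incidence)
#'   and `risky_fraction_target`.
#' @export
#' @examples
#' diarrhoea_or_to_two_state(3, 2, 1.1)  # risky fraction 2/3
diarrhoea_or_to_two_state <- function(baseline_episodes, target_episodes,
                                      per_episode_or) {
  stopifnot(is.numeric(baseline_episodes), baseline_episodes > 0,
            is.numeric(target_episodes), target_episodes >= 0,
            is.numeric(per_episode_or), per_episode_or > 0)
  if (target_episodes > baseline_episodes) {
    stop("incidence increases are not modelled by this mapping ",
         "(target episodes exceed baseline)")
  }
  list(
    odds_ratio = per_episode_or^baseline_episodes,
    risky_fraction_baseline = 1,
    risky_fraction_target = target_episodes / baseline_episodes
  )
}

#' Reduce diarrhoea incidence through water and sanitation scale-up
#'
#' Applies the direct-effect machinery ([single_reduction()] composed by
#' [combine_reductions()]) with episodes per child-year in place of a
#' mortality rate: each intervention's isolated proportional reduction in
#' incidence is computed from its effectiveness, affected fraction and
#' coverage change, and the composed reduction is applied to the baseline
#' incidence.
#'
#' @param baseline_episodes Mean episodes per child-year (>= 0).
#' @param effectiveness,affected_fraction,baseline_coverage,target_coverage
#'   Vectors over interventions (recycled), as for [single_reduction()].
#' @return Reduced episodes per child-year.
#' @export
reduce_diarrhoea_incidence <- function(baseline_episodes, effectiveness,
                                       affected_fraction = 1,
                                       baseline_coverage = 0,
                                       target_coverage = 0) {
  stopifnot(is.numeric(baseline_episodes), all(baseline_episodes >= 0))
  if (length(effectiveness) == 0L) return(baseline_episodes)
  r <- single_reduction(effectiveness, affected_fraction,
                        baseline_coverage, target_coverage)
  baseline_episodes * (1 - combine_reductions(r))
}

#' Reduce the fraction of children born with IUGR
#'
#' Intermittent preventive therapy or bednets in pregnancy, balanced energy
#' supplementation and multiple micronutrient supplementation reduce the
#' fraction of children born with intra-uterine growth restriction. The
#' calculation reuses the direct-effect machinery with the proportional
#' reduction applied to IUGR prevalence instead of a mortality rate.
#'
#' @param baseline_iugr Baseline fraction of births with IUGR.
#' @inheritParams reduce_diarrhoea_incidence
#' @return Reduced IUGR fraction.
#' @export
update_iugr <- function(baseline_iugr, effectiveness,
                        affected_fraction = 1,
                        baseline_coverage = 0, target_coverage = 0) {
  stopifnot(is_prop(baseline_iugr))
  if (length(effectiveness) == 0L) return(baseline_iugr)
  r <- single_reduction(effectiveness, affected_fraction,
                        baseline_coverage, target_coverage)
  baseline_iugr * (1 - combine_reductions(r))
}

#' Advance one age band of the stunting cohort
#'
#' Stunting in an age band is driven by up to five determinants: the carried
#' risk factor (IUGR for the neonatal band, previous-band stunting for later
#' bands), complementary feeding, diarrhoea episodes and zinc
#' supplementation. Each determinant's isolated proportional reduction in
#' stunting prevalence is obtained from the odds-ratio decomposition
#' machinery; the isolated reductions are then composed on remaining
#' prevalence exactly as intervention effects are composed on residual
#' mortality, and applied to the band's baseline stunting prevalence.
#'
#' @param baseline_stunting Baseline stunting prevalence of the band, in
#'   `(0, 1)`.
#' @param determinants List of determinants. Each element is a list with
#'   either a precomputed `reduction` (isolated proportional decline) or the
#'   triple `odds_ratio`, `baseline_risky_fraction`, `target_risky_fraction`,
#'   which is run through [solve_two_state()], [project_prevalence()] and
#'   [prevalence_reduction()] against `baseline_stunting`. Elements may carry
#'   a `source` field naming the intervention responsible (used for
#'   attribution).
#' @return List with `stunting` (updated prevalence) and `reductions`
#'   (isolated declines, named by determinant source).
#' @export
update_stunting_cohort <- function(baseline_stunting, determinants = list()) {
  stopifnot(is.numeric(baseline_stunting),
            baseline_stunting > 0, baseline_stunting < 1)
  red <- vapply(determinants, function(d) {
    if (!is.null(d$reduction)) return(d$reduction)
    if (d$baseline_risky_fraction == d$target_risky_fraction ||
        d$odds_ratio == 1) {
      return(0)
    }
    sol <- solve_two_state(d$odds_ratio, d$baseline_risky_fraction,
                           baseline_stunting)
    pt <- project_prevalence(sol$p_risky, sol$p_nonrisky,
                             d$target_risky_fraction)
    prevalence_reduction(baseline_stunting, pt)
  }, numeric(1))
  names(red) <- vapply(seq_along(determinants), function(i) {
    determinants[[i]]$source %||% paste0("determinant", i)
  }, "")
  list(
    stunting = baseline_stunting * (1 - combine_reductions(red)),
    reductions = red
  )
}

#' Shift breastfeeding category fractions under promotion scale-up
#'
#' Breastfeeding practice is described by four categories (exclusive,
#' predominant, partial, none) per age band. Promotion shifts children
#' toward improved practice through the same two-status odds-ratio solve
#' used for stunting, applied to the improved-versus-not dichotomy: the
#' risky status is "not reached by promotion" and the odds ratio is the odds
#' of improved breastfeeding without promotion relative to with promotion.
#' After the improved fraction is projected at the new coverage, categories
#' inside and outside the improved set are rescaled proportionally.
#'
#' @param fractions Named numeric vector over
#'   `c("exclusive", "predominant", "partial", "none")` summing to 1.
#' @param promotion_odds_ratio Odds of improved practice without promotion
#'   versus with promotion (> 0).
#' @param baseline_coverage,target_coverage Promotion coverage.
#' @param improved Character vector of categories counted as improved
#'   practice for this age band (default exclusive breastfeeding).
#' @return Updated named fractions summing to 1.
#' @export
update_breastfeeding <- function(fractions, promotion_odds_ratio,
                                 baseline_coverage, target_coverage,
                                 improved = "exclusive") {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0),
            promotion_odds_ratio > 0,
            is_prop(baseline_coverage), is_prop(target_coverage),
            all(improved %in% names(fractions)))
  p0 <- sum(fractions[improved])
  if (promotion_odds_ratio == 1 || baseline_coverage == target_coverage ||
      p0 <= 0 || p0 >= 1) {
    return(fractions)
  }
  sol <- solve_two_state(promotion_odds_ratio, 1 - baseline_coverage, p0)
  pt <- project_prevalence(sol$p_risky, sol$p_nonrisky, 1 - target_coverage)
  out <- fractions
  out[improved] <- fractions[improved] * pt / p0
  rest <- setdiff(names(fractions), improved)
  out[rest] <- fractions[rest] * (1 - pt) / (1 - p0)
  out
}
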