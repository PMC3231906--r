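#' Proportional mortality reduction from a single intervention
#'
#' Computes the proportional reduction in cause-specific mortality produced
#' by scaling one intervention's coverage from `baseline_coverage` to
#' `target_coverage`:
#' \deqn{R = \frac{I (C_t - C_0)}{1 - I C_0} \times AF}
#' where `I` is the effectiveness among those covered, `AF` the affected
#' fraction (share of the cause's deaths whose mechanism the intervention can
#' act on) and the denominator removes the impact already embedded in the
#' baseline mortality rate. The result is negative when coverage declines.
#'
#' @param effectiveness Proportion in `[0, 1]`.
#' @param affected_fraction Proportion in `[0, 1]`.
#' @param baseline_coverage,target_coverage Proportions in `[0, 1]`.
#' @return Proportional reduction (vectorised over its arguments).
#' @export
#' @examples
#' # ORS against diarrhoea mortality, coverage 25% -> 50%
#' single_reduction(0.93, 0.95, 0.25, 0.50)  # 0.288
single_reduction <- function(effectiveness, affected_fraction,
                             baseline_coverage, target_coverage) {
  stopifnot(is_prop(effectiveness), is_prop(affected_fraction),
            is_prop(baseline_coverage), is_prop(target_coverage))
  denom <- 1 - effectiveness * baseline_coverage
  if (any(denom <= 1e-12)) {
    stop("baseline coverage saturates the intervention (I * C0 = 1); ",
         "no residual mortality left to act on")
  }
  effectiveness * (target_coverage - baseline_coverage) / denom *
    affected_fraction
}

#' Compose isolated reductions on residual mortality
#'
#' The total reduction from several interventions acting on the same cause
#' is computed by letting each act on the mortality remaining after the
#' others: \deqn{R = 1 - \prod_i (1 - R_i).} The result does not depend on
#' the order of the inputs.
#'
#' @param reductions Numeric vector of isolated proportional reductions, each
#'   in `(-1, 1]`. An empty vector gives 0.
#' @return Combined proportional reduction.
#' @export
#' @examples
#' combine_reductions(c(0.288, 0.25))  # 0.466
combine_reductions <- function(reductions) {
  stopifnot(is.numeric(reductions), all(is.finite(reductions)),
            all(reductions > -1), all(reductions <= 1))
  1 - prod(1 - reductions)
}

#' Attribute shares of a combined reduction to interventions by timing
#'
#' Splits the combined mortality reduction for one (cause, age band) cell
#' across the contributing interventions. Tiers are processed in life-course
#' order ([timing_tiers()]): the earliest acting tier is credited as if it
#' worked on the entire cause-specific burden, and each later tier only on
#' the mortality remaining after all earlier tiers have acted. Within a tier,
#' interventions split the tier's block proportionally to their isolated
#' reductions. Shares sum to one whenever the total reduction is positive.
#'
#' Negative isolated reductions (coverage scale-down) are excluded from
#' attribution with a warning; the published calculus defines attribution
#' only for mortality declines.
#'
#' @param reductions Named numeric vector of isolated reductions per
#'   intervention (herd-adjusted where applicable).
#' @param tiers Named character vector mapping intervention id to a timing
#'   tier; defaults to everything in the last (curative) tier, which reduces
#'   to plain proportional attribution.
#' @return Named numeric vector of shares in `[0, 1]` summing to 1 (or all
#'   zero when the total reduction is zero).
#' @export
#' @examples
#' attribute_shares(c(ors = 0.288, zinc = 0.25))
#' attribute_shares(
#'   c(rota = 0.306, ors = 0.288, zinc = 0.25),
#'   tiers = c(rota = "vaccines", ors = "curative-after-birth",
#'             zinc = "curative-after-birth")
#' )
attribute_shares <- function(reductions, tiers = NULL) {
  if (length(reductions) == 0L) return(stats::setNames(numeric(0), character(0)))
  ids <- names(reductions)
  if (is.null(ids)) ids <- as.character(seq_along(reductions))
  names(reductions) <- ids
  if (is.null(tiers)) {
    tiers <- stats::setNames(rep("curative-after-birth", length(ids)), ids)
  }
  shares <- stats::setNames(rep(0, length(ids)), ids)

  if (any(reductions < 0)) {
    warning("negative reductions excluded from attribution: ",
            paste(ids[reductions < 0], collapse = ", "))
  }
  pos <- reductions[reductions > 0]
  if (length(pos) == 0L) return(shares)
  total <- combine_reductions(pos)
  if (total <= 0) return(shares)

  ranks <- tier_rank(tiers[names(pos)])
  surv_before <- 1  # product of (1 - R) over all strictly earlier tiers
  for (rk in sort(unique(ranks))) {
    in_tier <- names(pos)[ranks == rk]
    tier_surv <- prod(1 - pos[in_tier])
    block <- surv_before * (1 - tier_surv) / total
    shares[in_tier] <- block * pos[in_tier] / sum(pos[in_tier])
    surv_before <- surv_before * tier_surv
  }
  shares
}

#' Aggregate cause-specific reductions into an all-cause reduction
#'
#' The all-cause mortality reduction in an age band is the cause-fraction
#' weighted sum of the cause-specific combined reductions:
#' \eqn{\sum_j R_j f_j}.
#'
#' @param cause_reductions Named numeric vector of combined reductions per
#'   cause; causes absent from the vector contribute 0.
#' @param cause_fractions Named numeric vector of baseline cause-of-death
#'   fractions summing to 1.
#' @return All-cause proportional reduction.
#' @export
#' @examples
#' all_cause_reduction(c(diarrhoea = 0.46), c(diarrhoea = 0.2, other = 0.8))
all_cause_reduction <- function(cause_reductions, cause_fractions) {
  stopifnot(!is.null(names(cause_fractions)))
  if (abs(sum(cause_fractions) - 1) > 1e-6) {
    stop("cause fractions must sum to 1")
  }
  r <- cause_reductions[names(cause_fractions)]
  r[is.na(r)] <- 0
  sum(r * cause_fractions)
}
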