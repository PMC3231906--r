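#' Piecewise-linear herd-protection curve
#'
#' Herd protection of unvaccinated (or non-bednet-using) children is
#' modelled as a phenomenological function of population coverage: zero
#' below `lower`, `max_effect` above `upper`, and linearly interpolated in
#' between. The measles vaccine uses the curve (0.90, 0.95, 1.0): full herd
#' protection above 95% coverage, none below 90%.
#'
#' @param lower,upper Coverage thresholds, `0 <= lower < upper <= 1`.
#' @param max_effect Herd protection reached at `upper`, in `[0, 1]`.
#' @return An object of class `herd_curve`.
#' @export
#' @examples
#' measles <- herd_curve(0.90, 0.95, 1.0)
#' herd_value(measles, c(0.75, 0.925, 0.97))
herd_curve <- function(lower = 0.90, upper = 0.95, max_effect = 1.0) {
  stopifnot(is_prop(lower), is_prop(upper), is_prop(max_effect),
            lower < upper)
  structure(list(lower = lower, upper = upper, max_effect = max_effect),
            class = "herd_curve")
}

#' @rdname herd_curve
#' @param curve A [herd_curve()].
#' @param coverage Population coverage in `[0, 1]` (vectorised).
#' @export
herd_value <- function(curve, coverage) {
  stopifnot(inherits(curve, "herd_curve"), is_prop(coverage))
  frac <- (coverage - curve$lower) / (curve$upper - curve$lower)
  curve$max_effect * pmin(1, pmax(0, frac))
}

#' Incremental herd protection from a coverage change
#'
#' The additional mortality reduction attributable to herd protection when
#' coverage moves from `baseline_coverage` to `target_coverage` is the change
#' in herd effect adjusted for protection already present at baseline:
#' \deqn{H = \frac{HE_t - HE_0}{1 - HE_0}.}
#'
#' @inheritParams herd_value
#' @param baseline_coverage,target_coverage Coverages in `[0, 1]`.
#' @return Incremental herd protection (proportion).
#' @export
incremental_herd <- function(curve, baseline_coverage, target_coverage) {
  he0 <- herd_value(curve, baseline_coverage)
  het <- herd_value(curve, target_coverage)
  if (he0 >= 1) {
    stop("population already fully herd-protected at baseline coverage")
  }
  (het - he0) / (1 - he0)
}

#' Combine a direct reduction with herd protection
#'
#' The herd effect acts on the mortality remaining after the intervention's
#' direct effect: \deqn{hR = R + H (1 - R).} This is the residual-mortality
#' composition of the direct and herd components, so `total_with_herd(r, h)`
#' equals `combine_reductions(c(r, h))`.
#'
#' @param direct_reduction Direct proportional reduction `R`.
#' @param herd_increment Incremental herd protection `H` in `[0, 1]`.
#' @return Total proportional reduction, bounded by 1.
#' @export
#' @examples
#' total_with_herd(0.516, 1.0)  # full protection
total_with_herd <- function(direct_reduction, herd_increment) {
  stopifnot(is.numeric(direct_reduction), direct_reduction > -1,
            direct_reduction <= 1, is_prop(herd_increment))
  direct_reduction + herd_increment * (1 - direct_reduction)
}
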