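#' Z-score band labels
#'
#' Mortality risk with respect to height-for-age (and weight-for-height) is
#' defined over four bands of the international standard distribution:
#' below -3 SD, -3 to <-2 SD, -2 to <-1 SD and at or above -1 SD. Bands use
#' half-open intervals, with "stunted" meaning strictly below -2 SD.
#'
#' @return Character vector of the four band codes, most severe first.
#' @export
z_band_labels <- function() c("below_m3", "m3_to_m2", "m2_to_m1", "above_m1")

#' Place a prevalence on the international standard as four z-score bands
#'
#' Height-for-age (or weight-for-height) is assumed normally distributed
#' with standard deviation one on the international standard scale. The
#' population curve is the standard-shape normal shifted so that the mass
#' below the anchoring cut equals the observed prevalence; for stunting the
#' anchor is -2 SD, for severe wasting -3 SD. The shift is
#' \eqn{m = cut - \Phi^{-1}(p)} and band occupancies are successive
#' differences of \eqn{\Phi} at the shifted cuts -3, -2, -1. The mass below
#' the anchoring cut reproduces the input prevalence exactly.
#'
#' @param prevalence Observed prevalence in `(0, 1)`.
#' @param cut Anchoring cut on the international standard: `-2` (default,
#'   stunting / moderate-plus wasting) or `-3` (severe wasting).
#' @return Named numeric vector over [z_band_labels()] summing to 1.
#' @export
#' @examples
#' b <- prevalence_to_bands(0.50)
#' sum(b[c("below_m3", "m3_to_m2")])  # recovers 0.50
prevalence_to_bands <- function(prevalence, cut = -2) {
  stopifnot(is.numeric(prevalence), length(prevalence) == 1L,
            cut %in% c(-2, -3))
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly inside (0,1): the shifted-normal ",
         "placement is degenerate at 0 or 1")
  }
  shift <- cut - stats::qnorm(prevalence)
  q <- stats::pnorm(c(-3, -2, -1) - shift)
  stats::setNames(c(q[1], q[2] - q[1], q[3] - q[2], 1 - q[3]),
                  z_band_labels())
}

#' Band-occupancy-weighted average relative risk
#'
#' The average relative risk of death from a cause is the occupancy-weighted
#' mean of the band-specific relative risks, \eqn{ARR = \sum_s Z_s RR_s},
#' with the reference category (normal anthropometry, or the reference
#' breastfeeding/IUGR status) at RR = 1.
#'
#' @param occupancy Named numeric vector of category fractions summing to 1.
#' @param rr Named numeric vector of relative risks covering the categories
#'   of `occupancy`.
#' @return Average relative risk.
#' @export
#' @examples
#' average_relative_risk(
#'   c(below_m3 = 0.1, m3_to_m2 = 0.2, m2_to_m1 = 0.3, above_m1 = 0.4),
#'   c(below_m3 = 4.6, m3_to_m2 = 2.1, m2_to_m1 = 1.4, above_m1 = 1.0)
#' )
average_relative_risk <- function(occupancy, rr) {
  stopifnot(!is.null(names(occupancy)), !is.null(names(rr)),
            abs(sum(occupancy) - 1) < 1e-9)
  r <- rr[names(occupancy)]
  if (anyNA(r)) {
    stop("relative risks missing for category(ies): ",
         paste(names(occupancy)[is.na(r)], collapse = ", "))
  }
  sum(occupancy * r)
}

#' Mortality reduction from a change in average relative risk
#'
#' \eqn{R = 1 - ARR_t / ARR_0}: positive when the population risk profile
#' improves, negative when it worsens.
#'
#' @param arr_t Average relative risk in the projection year.
#' @param arr_0 Average relative risk at baseline (> 0).
#' @return Proportional mortality reduction.
#' @export
mortality_reduction_from_arr <- function(arr_t, arr_0) {
  stopifnot(is.numeric(arr_t), is.numeric(arr_0))
  if (arr_0 <= 0) stop("baseline average relative risk must be positive")
  1 - arr_t / arr_0
}

#' Redistribute severely wasted children under supplemental feeding
#'
#' Supplemental feeding is given only to severely wasted children (below
#' -3 SD weight-for-height). Children reached by the coverage increase are
#' moved into less severe bands of the international standard according to a
#' destination split; for some children feeding is ineffective and they stay
#' below -3 SD. Total mass is conserved.
#'
#' @param bands Named numeric vector over [z_band_labels()] summing to 1.
#' @param coverage_change Increase in supplemental feeding coverage, in
#'   `[0, 1]`.
#' @param destination_split Named numeric vector over
#'   `c("above_m1", "m2_to_m1", "m3_to_m2", "stay")` summing to 1: the
#'   fates of treated children.
#' @return Updated band occupancy summing to 1.
#' @export
apply_supplemental_feeding <- function(bands, coverage_change,
                                       destination_split) {
  dest <- c("above_m1", "m2_to_m1", "m3_to_m2", "stay")
  stopifnot(setequal(names(bands), z_band_labels()),
            abs(sum(bands) - 1) < 1e-9,
            is_prop(coverage_change),
            setequal(names(destination_split), dest),
            abs(sum(destination_split) - 1) < 1e-9,
            all(destination_split >= 0))
  treated <- coverage_change * bands[["below_m3"]]
  out <- bands
  for (b in c("above_m1", "m2_to_m1", "m3_to_m2")) {
    out[[b]] <- out[[b]] + treated * destination_split[[b]]
  }
  out[["below_m3"]] <- out[["below_m3"]] -
    treated * (1 - destination_split[["stay"]])
  out
}
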