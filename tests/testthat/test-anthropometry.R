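test_that("prevalence placement reproduces the shifted-normal geometry", {
  # at 50% stunting the curve is shifted so that -2 sits at the median:
  # the severe band holds pnorm(-1) of the population
  b <- prevalence_to_bands(0.50)
  expect_equal(unname(b["below_m3"]), pnorm(-1), tolerance = 1e-12)
  # at the international standard itself the shift vanishes
  b0 <- prevalence_to_bands(pnorm(-2))
  expect_equal(unname(b0["below_m3"]), pnorm(-3), tolerance = 1e-12)
  expect_error(prevalence_to_bands(0), "degenerate")
  expect_error(prevalence_to_bands(1), "degenerate")
})

test_that("band occupancies recover the input prevalence and conserve mass", {
  set.seed(77)
  for (p in c(runif(30, 0.005, 0.995))) {
    b <- prevalence_to_bands(p)
    expect_equal(unname(b["below_m3"] + b["m3_to_m2"]), p, tolerance = 1e-12)
    expect_equal(sum(b), 1, tolerance = 1e-12)
    expect_true(all(b >= 0))
    # severe-wasting anchor: mass below -3 equals the input
    b3 <- prevalence_to_bands(p, cut = -3)
    expect_equal(unname(b3["below_m3"]), p, tolerance = 1e-12)
  }
})

test_that("higher prevalence shifts mass leftward in every cumulative band", {
  ps <- seq(0.05, 0.95, by = 0.05)
  bands <- t(vapply(ps, prevalence_to_bands, numeric(4)))
  cum1 <- bands[, 1]
  cum2 <- bands[, 1] + bands[, 2]
  cum3 <- cum2 + bands[, 3]
  expect_true(all(diff(cum1) > 0))
  expect_true(all(diff(cum2) > 0))
  expect_true(all(diff(cum3) > 0))
})

test_that("average relative risk is the occupancy-weighted mean", {
  occ <- c(below_m3 = 0.1, m3_to_m2 = 0.2, m2_to_m1 = 0.3, above_m1 = 0.4)
  rr <- c(below_m3 = 4.6, m3_to_m2 = 2.1, m2_to_m1 = 1.4, above_m1 = 1.0)
  expect_equal(average_relative_risk(occ, rr), 1.70, tolerance = 1e-12)
  ref_only <- c(below_m3 = 0, m3_to_m2 = 0, m2_to_m1 = 0, above_m1 = 1)
  expect_equal(average_relative_risk(ref_only, rr), 1.0)
  expect_equal(average_relative_risk(occ, rr * 0 + 1), 1.0)
  # linear in the occupancy argument
  occ2 <- c(below_m3 = 0.4, m3_to_m2 = 0.3, m2_to_m1 = 0.2, above_m1 = 0.1)
  mix <- 0.3 * occ + 0.7 * occ2
  expect_equal(average_relative_risk(mix, rr),
               0.3 * average_relative_risk(occ, rr) +
                 0.7 * average_relative_risk(occ2, rr), tolerance = 1e-12)
})

test_that("mortality reduction follows the ARR ratio with sign convention", {
  expect_equal(mortality_reduction_from_arr(1.5, 1.5), 0)
  expect_equal(mortality_reduction_from_arr(1.36, 1.70), 0.2, tolerance = 1e-12)
  # a doubling of average risk is flagged as a worsening (negative reduction)
  expect_equal(mortality_reduction_from_arr(2, 1), -1)
  expect_error(mortality_reduction_from_arr(1.2, 0), "positive")
})

test_that("supplemental feeding redistributes severely wasted mass", {
  b <- c(below_m3 = 0.10, m3_to_m2 = 0.15, m2_to_m1 = 0.25, above_m1 = 0.50)
  split <- c(above_m1 = 0.2, m2_to_m1 = 0.3, m3_to_m2 = 0.3, stay = 0.2)
  expect_equal(apply_supplemental_feeding(b, 0, split), b)
  stay_all <- c(above_m1 = 0, m2_to_m1 = 0, m3_to_m2 = 0, stay = 1)
  expect_equal(apply_supplemental_feeding(b, 0.8, stay_all), b)
  out <- apply_supplemental_feeding(b, 1, split)
  expect_equal(unname(out["below_m3"]), 0.02, tolerance = 1e-12)
  expect_equal(unname(out["above_m1"]), 0.50 + 0.10 * 0.2, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  # partial coverage conserves mass too
  set.seed(8)
  for (i in 1:10) {
    dc <- runif(1)
    expect_equal(sum(apply_supplemental_feeding(b, dc, split)), 1,
                 tolerance = 1e-12)
  }
})
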