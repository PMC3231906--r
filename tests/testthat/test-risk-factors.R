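test_that("two-status solve reproduces the preventive-zinc stunting chain", {
  sol <- solve_two_state(1.18, 0.75, 0.35)
  expect_equal(round(sol$p_nonrisky, 3), 0.322)  # supplemented children
  expect_equal(round(sol$p_risky, 3), 0.359)     # unsupplemented children
  # supplementation scale-up from 25% to 50% coverage
  pt <- project_prevalence(sol$p_risky, sol$p_nonrisky, 0.50)
  expect_equal(round(pt, 3), 0.341)
  # baseline mix recovers the baseline prevalence exactly
  expect_equal(project_prevalence(sol$p_risky, sol$p_nonrisky, 0.75), 0.35,
               tolerance = 1e-12)
  expect_equal(round(prevalence_reduction(0.350, 0.341), 2), 0.03)
  expect_equal(prevalence_reduction(0.350, 0.341), 0.009 / 0.35,
               tolerance = 1e-12)
})

test_that("two-status solve matches a bisection oracle over random grids", {
  set.seed(101)
  for (i in 1:60) {
    or <- runif(1, 0.2, 5)
    fk <- runif(1, 0.05, 0.95)
    p <- runif(1, 0.05, 0.95)
    sol <- solve_two_state(or, fk, p)
    expect_lt(max(abs(two_state_residuals(sol, or, fk, p))), 1e-10)
    oracle <- bisect_two_state(or, fk, p)
    expect_equal(sol$p_nonrisky, oracle$p_nonrisky, tolerance = 1e-8)
    expect_equal(sol$p_risky, oracle$p_risky, tolerance = 1e-8)
    if (or > 1) {
      expect_gt(sol$p_risky, p)
      expect_lt(sol$p_nonrisky, p)
    }
  }
  # no risk differential: both statuses at the overall prevalence
  sol1 <- solve_two_state(1, 0.3, 0.4)
  expect_equal(sol1$p_risky, 0.4, tolerance = 1e-12)
  expect_equal(sol1$p_nonrisky, 0.4, tolerance = 1e-12)
})

test_that("project_prevalence is a plain mixture", {
  expect_equal(project_prevalence(0.2, 0.2, 0.77), 0.2)
  expect_equal(prevalence_reduction(0.4, 0.2), 0.5)
  expect_equal(prevalence_reduction(0.25, 0.25), 0)
  expect_error(prevalence_reduction(0, 0.1), "positive")
})

test_that("four-status solve satisfies all defining relations", {
  ors <- c(1.2, 1.5, 2.0)
  f <- c(0.4, 0.2, 0.2, 0.2)
  p <- solve_four_state(ors, f, 0.35)
  # mixture constraint
  expect_lt(abs(sum(f * p) - 0.35), 1e-10)
  # three odds-ratio relations against the reference state
  odds <- p / (1 - p)
  expect_equal(odds[-1] / odds[1], ors, tolerance = 1e-10)
  # degenerate cases
  expect_equal(unname(solve_four_state(c(1, 1, 1), f, 0.35)), rep(0.35, 4),
               tolerance = 1e-10)
  p_one <- solve_four_state(ors, c(0, 1, 0, 0), 0.35)
  expect_equal(unname(p_one[2]), 0.35, tolerance = 1e-10)
})

test_that("four-status solve degenerates to the two-status closed form", {
  or_k <- 1.18
  p4 <- solve_four_state(c(or_k, 2, 3), c(0.25, 0.75, 0, 0), 0.35)
  sol <- solve_two_state(or_k, 0.75, 0.35)
  expect_equal(unname(p4[1]), sol$p_nonrisky, tolerance = 1e-10)
  expect_equal(unname(p4[2]), sol$p_risky, tolerance = 1e-10)
})

test_that("diarrhoea incidence maps onto a two-status model", {
  m <- diarrhoea_or_to_two_state(3, 2, 1.1)
  expect_equal(m$risky_fraction_target, 2 / 3)
  expect_equal(round(m$risky_fraction_target, 3), 0.667)
  expect_equal(m$odds_ratio, 1.1^3)
  expect_equal(diarrhoea_or_to_two_state(4, 4, 1.2)$risky_fraction_target, 1)
  expect_equal(diarrhoea_or_to_two_state(3, 0, 1.2)$risky_fraction_target, 0)
  expect_error(diarrhoea_or_to_two_state(2, 3, 1.1), "increase")
  # population OR is monotone in episodes when the per-episode OR exceeds 1
  i <- seq(0.5, 6, by = 0.5)
  expect_true(all(diff(1.1^i) > 0))
})

test_that("incidence and IUGR scale-downs reuse the coverage machinery", {
  expect_equal(reduce_diarrhoea_incidence(3, numeric(0)), 3)
  expect_equal(reduce_diarrhoea_incidence(3, 0.3, 1, 0, 1), 2.1)
  # two interventions compose on remaining incidence
  expect_equal(reduce_diarrhoea_incidence(3, c(0.3, 0.2), 1, 0, 1),
               3 * (1 - 0.3) * (1 - 0.2))
  expect_equal(update_iugr(0.15, numeric(0)), 0.15)
  expect_equal(update_iugr(0.15, 0.2, 1, 0, 0.5), 0.15 * (1 - 0.1))
  expect_equal(update_iugr(0.15, c(0.2, 0.4), 1, 0, 1),
               0.15 * (1 - 0.2) * (1 - 0.4))
})

test_that("stunting cohort update composes isolated determinant declines", {
  expect_equal(update_stunting_cohort(0.35, list())$stunting, 0.35)
  # preventive zinc alone: 35% falls to 34.1%
  upd <- update_stunting_cohort(0.35, list(
    list(source = "zinc", odds_ratio = 1.18,
         baseline_risky_fraction = 0.75, target_risky_fraction = 0.50)))
  expect_equal(round(upd$stunting, 3), 0.341)
  # two precomputed determinants compose multiplicatively on remainder
  upd2 <- update_stunting_cohort(0.35, list(
    list(source = "a", reduction = 0.027),
    list(source = "b", reduction = 0.05)))
  expect_equal(upd2$stunting, 0.35 * (1 - 0.027) * (1 - 0.05),
               tolerance = 1e-12)
})

test_that("improving any determinant never increases stunting", {
  set.seed(202)
  for (i in 1:20) {
    p0 <- runif(1, 0.1, 0.5)
    f0 <- runif(1, 0.3, 0.9)
    det <- list(list(source = "x", odds_ratio = runif(1, 1, 3),
                     baseline_risky_fraction = f0,
                     target_risky_fraction = runif(1, 0, f0)))
    expect_lte(update_stunting_cohort(p0, det)$stunting, p0 + 1e-12)
  }
})

test_that("breastfeeding promotion shifts categories consistently", {
  f <- c(exclusive = 0.3, predominant = 0.2, partial = 0.3, none = 0.2)
  expect_equal(update_breastfeeding(f, 0.6, 0.2, 0.2), f)  # no coverage change
  expect_equal(update_breastfeeding(f, 1.0, 0.2, 0.6), f)  # OR = 1
  out <- update_breastfeeding(f, 1.5, 0.2, 0.6)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  # the projected improved fraction satisfies the odds and mixture relations
  sol <- solve_two_state(1.5, 0.8, 0.3)
  expect_lt(max(abs(two_state_residuals(sol, 1.5, 0.8, 0.3))), 1e-10)
  expect_equal(unname(out["exclusive"]),
               project_prevalence(sol$p_risky, sol$p_nonrisky, 0.4),
               tolerance = 1e-12)
  # non-improved categories keep their relative proportions
  expect_equal(unname(out["predominant"] / out["partial"]),
               unname(f["predominant"] / f["partial"]), tolerance = 1e-12)
})
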