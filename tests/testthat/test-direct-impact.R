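test_that("single_reduction reproduces the textbook coverage scale-ups", {
  # ORS: I = 0.93, AF = 0.95, coverage 25% -> 50% gives a 28.8% reduction
  expect_equal(single_reduction(0.93, 0.95, 0.25, 0.50),
               0.93 * 0.25 / (1 - 0.93 * 0.25) * 0.95, tolerance = 1e-12)
  expect_equal(round(single_reduction(0.93, 0.95, 0.25, 0.50), 3), 0.288)
  # measles vaccine: I = 0.85, AF = 1, coverage 75% -> 97%
  expect_equal(round(single_reduction(0.85, 1, 0.75, 0.97), 3), 0.516)
  # no coverage change -> no reduction, for any effectiveness
  expect_equal(single_reduction(0.8, 0.6, 0.4, 0.4), 0)
  # coverage decline -> negative reduction
  expect_lt(single_reduction(0.8, 1, 0.5, 0.3), 0)
})

test_that("single_reduction rejects a saturated baseline", {
  expect_error(single_reduction(1, 1, 1, 1), "saturat")
})

test_that("combine_reductions composes on residual mortality", {
  expect_equal(combine_reductions(c(0.288, 0.25)), 0.466)
  expect_equal(signif(combine_reductions(c(0.306, 0.288, 0.25)), 3), 0.629)
  expect_equal(combine_reductions(numeric(0)), 0)
  expect_equal(combine_reductions(0.37), 0.37)
})

test_that("combine_reductions is permutation-invariant and monotone", {
  set.seed(42)
  for (i in 1:25) {
    r <- runif(sample(2:6, 1))
    expect_equal(combine_reductions(r), combine_reductions(sample(r)),
                 tolerance = 1e-12)
    # monotone non-decreasing in each argument
    j <- sample(length(r), 1)
    r2 <- r
    r2[j] <- min(1, r[j] + 0.1)
    expect_gte(combine_reductions(r2), combine_reductions(r))
  }
})

test_that("single-tier attribution is plain proportional sharing", {
  s <- attribute_shares(c(ors = 0.288, zinc = 0.25))
  expect_equal(round(unname(s), 3), c(0.535, 0.465))
  expect_equal(sum(s), 1, tolerance = 1e-12)
  # oracle: with one tier the shares are exactly R_i / sum(R_i)
  set.seed(7)
  for (i in 1:10) {
    r <- runif(sample(2:5, 1), 0.05, 0.9)
    names(r) <- paste0("i", seq_along(r))
    expect_equal(attribute_shares(r), r / sum(r), tolerance = 1e-12)
  }
  expect_equal(unname(attribute_shares(c(solo = 0.4))), 1)
})

test_that("tiered attribution credits early tiers with the full burden", {
  s <- attribute_shares(
    c(rota = 0.306, ors = 0.288, zinc = 0.25),
    tiers = c(rota = "vaccines", ors = "curative-after-birth",
              zinc = "curative-after-birth"))
  total <- combine_reductions(c(0.306, 0.288, 0.25))
  expect_equal(unname(s["rota"]), 0.306 / total, tolerance = 1e-12)
  expect_equal(round(unname(s), 3), c(0.486, 0.275, 0.239))
  expect_equal(sum(s), 1, tolerance = 1e-12)
})

test_that("attribution shares sum to one for random tier assignments", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(2:7, 1)
    r <- setNames(runif(n, 0.01, 0.8), paste0("i", 1:n))
    tiers <- setNames(sample(timing_tiers(), n, replace = TRUE), names(r))
    s <- attribute_shares(r, tiers)
    expect_equal(sum(s), 1, tolerance = 1e-9)
    expect_true(all(s >= 0))
  }
})

test_that("negative reductions are excluded from attribution with a warning", {
  expect_warning(s <- attribute_shares(c(up = 0.3, down = -0.2)), "down")
  expect_equal(unname(s), c(1, 0))
  # all-zero total: shares are defined as zero
  expect_equal(unname(attribute_shares(c(a = 0, b = 0))), c(0, 0))
})

test_that("all-cause aggregation weights causes by their death fractions", {
  # 46% diarrhoea reduction on a 20% cause fraction: ~9% of all deaths
  f <- c(diarrhoea = 0.2, pneumonia = 0.3, other = 0.5)
  expect_equal(all_cause_reduction(c(diarrhoea = 0.46), f), 0.092)
  expect_equal(all_cause_reduction(c(diarrhoea = 0, pneumonia = 0), f), 0)
  expect_equal(all_cause_reduction(
    c(diarrhoea = 1, pneumonia = 1, other = 1), f), 1)
  expect_error(all_cause_reduction(c(diarrhoea = 0.3), c(diarrhoea = 0.5)),
               "sum to 1")
})
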