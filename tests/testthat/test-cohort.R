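test_that("single-band deaths averted follow the closed form", {
  sc <- tiny_scenario(reduction = 0.466)
  led <- project_cohort(sc)
  d <- led$deaths[led$deaths$year == 2011 & led$deaths$age_band == "0m" &
                    led$deaths$cause == "diarrhoea", ]
  # 1000 births, neonatal risk 0.03, diarrhoea fraction 0.2: 6 baseline
  # deaths, reduced by 46.6%
  expect_equal(d$deaths_baseline, 6, tolerance = 1e-9)
  expect_equal(d$deaths, 6 * (1 - 0.466), tolerance = 1e-9)
  expect_equal(d$averted, 6 * 0.466, tolerance = 1e-9)
})

test_that("neonatal survivors spill over into the next band", {
  sc <- tiny_scenario(reduction = 0.466)
  led <- project_cohort(sc)
  e <- led$entrants
  neo_averted <- sum(led$deaths$averted[led$deaths$year == 2011 &
                                          led$deaths$age_band == "0m"])
  gain <- e$entrants[e$year == 2011 & e$age_band == "1-5m"] -
    e$entrants_baseline[e$year == 2011 & e$age_band == "1-5m"]
  expect_equal(gain, neo_averted, tolerance = 1e-9)
  expect_gt(gain, 0)
})

test_that("flat coverage yields a stationary ledger with zero impact", {
  sc <- random_country_scenario(19, n_interventions = 8, n_years = 5,
                                flat = TRUE)
  led <- project_cohort(sc)
  expect_equal(max(abs(led$deaths$averted)), 0, tolerance = 1e-12)
  expect_equal(nrow(led$averted_by_intervention), 0)
  # constant births + constant mortality: deaths per band identical each year
  tot <- aggregate(deaths ~ year + age_band, led$deaths, sum)
  for (b in band_labels()) {
    expect_equal(diff(range(tot$deaths[tot$age_band == b])), 0,
                 tolerance = 1e-9)
  }
  r <- summarize_rates(led)
  expect_equal(diff(range(r$u5mr)), 0, tolerance = 1e-9)
})

test_that("attributed deaths averted conserve the cell totals", {
  sc <- random_country_scenario(23, n_interventions = 10, n_years = 6)
  red <- compute_reductions(sc)
  led <- project_cohort(sc, red)
  det <- aggregate(averted ~ year + age_band + cause, led$averted_detail, sum)
  m <- merge(det, led$deaths, by = c("year", "age_band", "cause"),
             suffixes = c("_attr", "_total"))
  expect_gt(nrow(m), 0)
  expect_lt(max(abs(m$averted_attr - m$averted_total)), 1e-9)
  # intervention-level table is the aggregate of the detail
  byiv <- aggregate(averted ~ year + intervention, led$averted_detail, sum)
  m2 <- merge(byiv, led$averted_by_intervention,
              by = c("year", "intervention"))
  expect_lt(max(abs(m2$averted.x - m2$averted.y)), 1e-12)
})

test_that("scale-up never increases total deaths", {
  sc <- random_country_scenario(31, n_interventions = 10, n_years = 6)
  led <- project_cohort(sc)
  tot <- aggregate(cbind(deaths, deaths_baseline) ~ year, led$deaths, sum)
  expect_true(all(tot$deaths <= tot$deaths_baseline + 1e-9))
})

test_that("rates follow the survival product over band risks", {
  sc <- tiny_scenario(reduction = 0, neonatal_risk = 0.03)
  sc$mortality[["1-5m"]]$risk <- 0.01
  sc$mortality[["6-11m"]]$risk <- 0.01
  led <- project_cohort(sc)
  r <- summarize_rates(led)
  expect_equal(r$nmr_baseline[1], 30)
  expect_equal(r$imr_baseline[1], (1 - 0.97 * 0.99 * 0.99) * 1000,
               tolerance = 1e-9)
  u5 <- (1 - 0.97 * 0.99 * 0.99 * (1 - 0.005) * (1 - 0.006)) * 1000
  expect_equal(r$u5mr_baseline[1], u5, tolerance = 1e-9)
})

test_that("a missing trajectory year is reported by name", {
  sc <- tiny_scenario()
  sc$coverage <- sc$coverage[sc$coverage$year != 2011, ]
  expect_error(compute_reductions(sc), "missing year 2011")
})
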