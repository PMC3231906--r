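test_that("the demo bundle validates and reproduces the effect chains", {
  sc <- demo_scenario()
  expect_identical(validate_scenario(sc), character(0))
  red <- compute_reductions(sc)
  pe <- red$per_entity
  final <- sc$final_year
  r_of <- function(id) {
    unique(pe$reduction[pe$year == final & pe$entity == id &
                          pe$cause == "diarrhoea" & pe$age_band == "1-5m"])
  }
  expect_equal(round(r_of("ors"), 3), 0.288)
  expect_equal(r_of("zinc_treatment"), 0.25, tolerance = 1e-12)
  expect_equal(r_of("rotavirus_vaccine"), 0.306, tolerance = 1e-12)
  # measles at 97% coverage: herd effect completes the protection
  rm <- pe$reduction[pe$year == final & pe$entity == "measles_vaccine" &
                       pe$age_band == "1-5m"]
  expect_equal(unique(rm), 1, tolerance = 1e-12)
  # combined diarrhoea reduction includes the direct trio composed on
  # residual mortality plus the indirect (nutrition) routes
  comb <- red$combined$reduction[red$combined$year == final &
                                   red$combined$cause == "diarrhoea" &
                                   red$combined$age_band == "1-5m"]
  expect_gte(comb, combine_reductions(c(0.288, 0.25, 0.306)) - 1e-9)
  expect_lte(comb, 1)
  # hand washing at full scale-up cuts incidence from 3 to 2 episodes
  tr <- red$trajectories
  expect_equal(tr$diarrhoea_episodes[tr$year == final &
                                       tr$age_band == "1-5m"], 2,
               tolerance = 1e-9)
})

test_that("the same seed reproduces a byte-identical bundle", {
  a <- random_country_scenario(7, n_interventions = 8, n_years = 4)
  b <- random_country_scenario(7, n_interventions = 8, n_years = 4)
  pa <- withr::local_tempfile(fileext = ".json")
  pb <- withr::local_tempfile(fileext = ".json")
  write_scenario(a, pa)
  write_scenario(b, pb)
  expect_identical(readLines(pa), readLines(pb))
  # a different seed gives a different bundle
  write_scenario(random_country_scenario(8, n_interventions = 8, n_years = 4),
                 pb)
  expect_false(identical(readLines(pa), readLines(pb)))
})

test_that("generated bundles always validate", {
  for (s in 1:5) {
    sc <- random_country_scenario(s, n_interventions = 7, n_years = 4)
    expect_identical(validate_scenario(sc), character(0))
  }
})

test_that("the generator does not disturb the session RNG state", {
  set.seed(555)
  x <- runif(1)
  set.seed(555)
  invisible(random_country_scenario(3, n_interventions = 6, n_years = 3))
  expect_identical(runif(1), x)
})

test_that("run_scenario writes deterministic report tables", {
  sc <- random_country_scenario(12, n_interventions = 8, n_years = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out <- run_scenario(sc, d1)
  expect_setequal(list.files(d1),
                  c("rates.csv", "deaths.csv",
                    "deaths_averted_by_intervention.csv", "nutrition.csv"))
  run_scenario(sc, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_s3_class(out$rates, "data.frame")
})

test_that("run_scenario refuses an invalid bundle with diagnostics", {
  sc <- demo_scenario()
  sc$mortality[["12-23m"]] <- NULL
  d <- withr::local_tempdir()
  expect_error(run_scenario(sc, d), "12-23m|age bands")
})
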