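test_that("water years run October through September", {
  expect_equal(
    water_year(lubridate::as_datetime(c(
      "2014-10-01 00:00:00", "2015-06-15 12:00:00", "2015-09-30 23:00:00",
      "2015-10-01 00:00:00"
    ))),
    c(2015, 2015, 2015, 2016)
  )
})

test_that("budget shares are computed from the ledger and sum to 100%", {
  sim <- fake_sim(
    list(
      "weathering_vadose.o" = 60, "wet_dep_vadose.n" = 40,
      "uptake_vadose.n" = 30, "denitrification_vadose.n" = 70
    ),
    days = 365
  )
  bud <- annual_budget(sim, 2015)
  src <- dplyr::filter(bud, category == "source")
  expect_equal(sum(src$share_pct), 100, tolerance = 1e-9)
  expect_equal(
    src$share_pct[src$flux == "mancos"], 60, tolerance = 1e-9
  )
  expect_equal(src$mol_yr[src$flux == "mancos"], 60 * 365,
    tolerance = 1e-9)
  snk <- dplyr::filter(bud, category == "sink")
  expect_equal(sum(snk$share_pct), 100, tolerance = 1e-9)
  expect_equal(attr(bud, "mancos_share_pct"), 60, tolerance = 1e-9)
})

test_that("weathering-only ledgers attribute all sources to the shale", {
  sim <- fake_sim(list("weathering_vadose.o" = 5, "weathering_gw.o" = 1))
  bud <- annual_budget(sim, 2015)
  expect_equal(attr(bud, "mancos_share_pct"), 100)
  expect_equal(attr(bud, "mancos_new_share_pct"), 100)
})

test_that("partial water years are refused unless requested", {
  sim <- fake_sim(list("wet_dep_vadose.n" = 1), days = 100)
  expect_error(annual_budget(sim, 2015), "partially covered")
  expect_silent(bud <- annual_budget(sim, 2015, partial = TRUE))
  expect_equal(
    bud$mol_yr[bud$flux == "wet_dep"], 100, tolerance = 1e-9
  )
})

test_that("ledger weathering matches its closed form on any forcing", {
  d <- east_river_subwatersheds()
  f <- generate_forcing(forcing_config(seed = 13, n_years = 1), d)
  sim <- simulate_watershed(f, "C2", d, duration_days = 15, quiet = TRUE)
  got <- riverN:::sum_ledger_kinds(
    sim, c("weathering_vadose", "weathering_gw")
  )
  want <- mancos_annual_source(
    load_scenario("C2")$weathering, d, days = 15
  )
  expect_rel_equal(got, want, tol = 1e-9)
})

test_that("calibration balance checks flag the +/-10% band", {
  pass <- fake_sim(list(
    "uptake_vadose.n" = 100, "litter.o" = 55, "cattle.o" = 50,
    "wet_dep_vadose.n" = 100, "denitrification_vadose.n" = 95
  ))
  chk <- balance_checks(pass)
  expect_equal(chk$ratio[chk$check == "litter_plus_cattle_vs_uptake"],
    1.05, tolerance = 1e-9)
  expect_true(chk$pass[chk$check == "litter_plus_cattle_vs_uptake"])
  fail <- fake_sim(list("uptake_vadose.n" = 100, "litter.o" = 120))
  chk2 <- balance_checks(fail)
  expect_false(chk2$pass[chk2$check == "litter_plus_cattle_vs_uptake"])
  # zero uptake is indeterminate, not a pass
  none <- fake_sim(list("litter.o" = 10))
  chk3 <- balance_checks(none)
  expect_true(is.na(chk3$ratio[1]))
  expect_false(chk3$pass[1])
})

test_that("RMSE matches hand arithmetic and ignores row order", {
  ts <- seq(
    lubridate::as_datetime("2015-01-01", tz = "UTC"),
    by = "hour", length.out = 3
  )
  mod <- tibble::tibble(
    timestamp = ts, subwatershed = "LT", compartment = "stream",
    species = "no3", mol = 1, uM = c(2, 2, 2)
  )
  obs <- tibble::tibble(
    timestamp = ts, subwatershed = "LT", species = "no3",
    concentration_uM = c(1, 2, 3)
  )
  expect_rel_equal(
    rmse_concentration(obs, mod, "no3", "LT"), sqrt(2 / 3), tol = 1e-12
  )
  expect_equal(
    rmse_concentration(obs[c(3, 1, 2), ], mod, "no3", "LT"),
    rmse_concentration(obs, mod, "no3", "LT")
  )
  # identical series score zero; constant offset d scores d
  obs2 <- obs
  obs2$concentration_uM <- c(2, 2, 2)
  expect_equal(rmse_concentration(obs2, mod, "no3", "LT"), 0)
  obs3 <- obs
  obs3$concentration_uM <- c(2.5, 2.5, 2.5)
  expect_equal(rmse_concentration(obs3, mod, "no3", "LT"), 0.5)
  expect_error(
    rmse_concentration(obs, mod, "no3", "EAQ"), "no observations"
  )
})

test_that("scenario comparison reports deltas on shared forcing", {
  d <- east_river_subwatersheds()
  f <- generate_forcing(forcing_config(seed = 17, n_years = 1), d)
  h <- derive_hydro_fluxes(f, d, quiet = TRUE)
  base <- simulate_watershed(
    hydro = h, scenario = "C2", descriptors = d,
    duration_days = 10, quiet = TRUE
  )
  same <- simulate_watershed(
    hydro = h, scenario = "C2", descriptors = d,
    duration_days = 10, quiet = TRUE
  )
  nc <- simulate_watershed(
    hydro = h, scenario = "NC", descriptors = d,
    duration_days = 10, quiet = TRUE
  )
  rep1 <- compare_scenarios(list(a = base, b = same))
  expect_equal(nrow(rep1), 2 * 5) # runs x sub-watersheds
  expect_equal(max(abs(rep1$delta_peak_no3)), 0)
  rep2 <- compare_scenarios(list(C2 = base, NC = nc))
  # the no-cattle run has no cattle flux but identical external inputs
  expect_equal(
    riverN:::sum_ledger_kinds(nc, "cattle"), 0
  )
  expect_equal(
    riverN:::sum_ledger_kinds(nc, c("wet_dep_vadose", "dry_dep",
      "weathering_vadose", "weathering_gw", "fixation")),
    riverN:::sum_ledger_kinds(base, c("wet_dep_vadose", "dry_dep",
      "weathering_vadose", "weathering_gw", "fixation"))
  )
  # mismatched forcing is refused
  f2 <- generate_forcing(forcing_config(seed = 18, n_years = 1), d)
  other <- simulate_watershed(f2, "C2", d, duration_days = 10,
    quiet = TRUE)
  expect_error(compare_scenarios(list(a = base, b = other)), "forcing")
})
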