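test_that("soil temperature factor matches its reference identities", {
  expect_equal(soil_temperature_factor(5), 1)
  expect_equal(soil_temperature_factor(7), 12)
  expect_equal(soil_temperature_factor(3), 1 / 12)
  expect_warning(soil_temperature_factor(20), "1e6")
})

test_that("land-cover weighting combines per-cover rate constants", {
  lt <- east_river_subwatersheds()[5, ] # LT row
  zero_cover <- lt
  zero_cover[, c(
    "frac_deciduous", "frac_coniferous", "frac_meadow", "frac_willow"
  )] <- 0
  k <- c(df = 0.3, cf = 0.2, ms = 0.05, ww = 0.09)
  expect_equal(landcover_weighted_rate(k, zero_cover, alpha = 1), 0)
  single <- one_basin_descriptors(frac_meadow = 1)
  expect_equal(
    landcover_weighted_rate(c(df = 0, cf = 0, ms = 0.05, ww = 0), single,
      alpha = 1), 0.05
  )
  # hand arithmetic for the LT land-cover mix with uniform meadow rates
  k2 <- c(df = 0.05, cf = 0.05, ms = 0.05, ww = 0.09)
  by_hand <- 0.05 * 0.330 + 0.05 * 0.135 + 0.05 * 0.422 + 0.09 * 0.075
  expect_equal(landcover_weighted_rate(k2, lt, alpha = 1), by_hand)
  # the temperature factor scales linearly
  expect_equal(
    landcover_weighted_rate(k2, lt, alpha = 12),
    12 * by_hand
  )
})

test_that("maximum uptake flux scales with area and temperature", {
  d <- one_basin_descriptors(frac_meadow = 1, area_m2 = 1e6)
  up <- uptake_params(f_max = rbind(
    df = c(a = 0, n = 0, o = 0), cf = c(a = 0, n = 0, o = 0),
    ms = c(a = 1e-5, n = 1e-5, o = 1e-5), ww = c(a = 0, n = 0, o = 0)
  ))
  expect_equal(max_uptake_flux(d, up, alpha = 0, species = "a"), 0)
  expect_equal(max_uptake_flux(d, up, alpha = 1, species = "n"), 10)
  d2 <- d
  d2$area_m2 <- 2e6
  expect_equal(
    max_uptake_flux(d2, up, alpha = 1, species = "n"),
    2 * max_uptake_flux(d, up, alpha = 1, species = "n")
  )
})

test_that("Monod uptake saturates below the maximum", {
  expect_equal(monod_uptake_flux(0, 100, 10, 0.1), 0)
  # half saturation at N = K_m * V_s
  expect_equal(monod_uptake_flux(10, 100, 10, 0.1), 5)
  expect_equal(monod_uptake_flux(30, 100, 10, 0.1), 7.5)
  expect_error(monod_uptake_flux(10, 0, 10, 0.1), "positive")
  for (n in 10^(0:6)) {
    expect_lt(monod_uptake_flux(n, 100, 10, 0.1), 10)
  }
})

test_that("deposition fluxes follow concentration x water flux", {
  dep <- deposition_params()
  d <- one_basin_descriptors(area_m2 = 1e6)
  fl <- deposition_fluxes(dep, d, water_flux_m3_day = 0, "vadose")
  expect_equal(unname(fl$wet), c(0, 0, 0))
  fl2 <- deposition_fluxes(dep, d, water_flux_m3_day = 1000, "vadose")
  expect_equal(fl2$wet[["n"]], 11) # 0.011 mol/m3 x 1000 m3/day
  # stream target receives no dry deposition
  fl3 <- deposition_fluxes(dep, d, water_flux_m3_day = 500, "stream")
  expect_equal(unname(fl3$dry), c(0, 0, 0))
  # negative net water flux removes N unless clamped
  fl4 <- deposition_fluxes(dep, d, -1000, "vadose")
  expect_equal(fl4$wet[["n"]], -11)
  depc <- deposition_params(clamp_wet_deposition = TRUE)
  fl5 <- deposition_fluxes(depc, d, -1000, "vadose")
  expect_equal(fl5$wet[["n"]], 0)
})

test_that("the 25%-of-TDN rule reproduces the reported DON deposition", {
  # wet: derived from 0.011 + 0.0068 mol/m3; reported rounded as 0.0058
  expect_equal(don_from_tdn_rule(0.011, 0.0068), 0.0178 / 3)
  expect_lt(abs(don_from_tdn_rule(0.011, 0.0068) - 0.0058), 2e-4)
  # dry: derived from the monitoring record's printed areal rates
  expect_lt(abs(don_from_tdn_rule(0.28, 1.29) - 0.52), 5e-3)
})

test_that("weathering fluxes partition between saprolite and bedrock", {
  lt <- east_river_subwatersheds()[5, ] # LT: sigma 0.18, A 1.49e7
  w <- weathering_params(M_a = 2e-7, M_n = 7.5e-6, M_o = 7.5e-6)
  fl <- weathering_fluxes(w, lt)
  expect_equal(fl$vadose[["o"]], 0.9 * 7.5e-6 * 0.18 * 1.49e7)
  expect_equal(fl$groundwater[["o"]], 0.1 * 7.5e-6 * 1.49e7)
  w0 <- weathering_params(M_a = 0, M_n = 0, M_o = 0)
  expect_equal(sum(unlist(weathering_fluxes(w0, lt))), 0)
  wm <- weathering_params(groundwater_area_mode = "mancos_area")
  expect_equal(
    weathering_fluxes(wm, lt)$groundwater[["o"]],
    0.1 * 7.5e-6 * 0.18 * 1.49e7
  )
  # annualized areal DON weathering sits in the reported range
  annual <- mol_m2_day_to_mol_ha_yr(7.5e-6)
  expect_gte(annual, 27)
  expect_lte(annual, 82.5)
})

test_that("fixation is temperature-gated, seeded and uniform", {
  fx <- fixation_params()
  d <- one_basin_descriptors(frac_meadow = 0.5, area_m2 = 1e6)
  expect_equal(fixation_flux(fx, d, t_soil_C = -2, areal_draw = 1e-5), 0)
  # fixer area = 1% of meadow cover
  expect_equal(
    fixation_flux(fx, d, t_soil_C = 5, areal_draw = 1e-5),
    1e-5 * 0.01 * 0.5 * 1e6
  )
  set.seed(123)
  a <- fixation_flux(fx, d, rep(5, 10))
  set.seed(123)
  b <- fixation_flux(fx, d, rep(5, 10))
  expect_identical(a, b)
  set.seed(42)
  draws <- runif(1e5, fx$lower, fx$upper)
  expect_lt(
    abs(mean(draws) - (fx$lower + fx$upper) / 2) /
      ((fx$lower + fx$upper) / 2), 0.02
  )
})

test_that("spruce GPP and litterfall follow their fitted response", {
  expect_equal(gpp_spruce(0), 1.51 / 1.2375)
  # warm-air asymptote
  expect_rel_equal(gpp_spruce(100), 1.51 / 0.2375, tol = 1e-6)
  lp <- litter_params(
    deciduous = c(0, 0, 0), meadow = c(0, 0), willow = c(0, 0, 0),
    upsilon = 0.4
  )
  d <- one_basin_descriptors()
  d$frac_meadow <- 0
  d$frac_coniferous <- 1
  got <- litter_flux(lp, d, doy = 100, t_air_C = 0)
  want <- 0.4 * 0.0057 * exp(-0.293 * gpp_spruce(0)) * 1e6 / 14
  expect_equal(got, want)
  # interval rates: deciduous day 100 -> first value, day 200 -> second
  lp2 <- litter_params(
    deciduous = c(0.001, 5e-6, 0.002), meadow = c(0, 0),
    willow = c(0, 0, 0), upsilon = 0
  )
  d2 <- one_basin_descriptors()
  d2$frac_meadow <- 0
  d2$frac_deciduous <- 1
  expect_equal(litter_flux(lp2, d2, 100, 0), 0.001 * 1e6 / 14)
  expect_equal(litter_flux(lp2, d2, 200, 0), 5e-6 * 1e6 / 14)
  expect_equal(litter_flux(lp2, d2, 300, 0), 0.002 * 1e6 / 14)
})

test_that("cattle DON delivery follows the grazing rotation", {
  ca <- cattle_params()
  expect_equal(cattle_don_flux(ca, "LT", 100), 0) # herd absent
  expect_equal(cattle_don_flux(ca, "LT", 200), 500 * (8.6 + 15)) # 11800
  expect_equal(cattle_don_flux(ca, "ME", 260), 0.6 * 11800) # 7080
  expect_equal(cattle_don_flux(ca, "EAQ", 260), 0.1 * 11800)
  expect_error(
    cattle_params(schedule = tibble::tibble(
      start_doy = c(1, 50), end_doy = c(100, 150), id = "LT", G = 0.5
    )),
    "overlapping"
  )
})

test_that("interflow and exchange fluxes follow their rating forms", {
  expect_equal(interflow_nitrogen_flux(100, 10, beta = 1), 0)
  expect_equal(interflow_nitrogen_flux(100, 10, beta = 0.4), 6)
  expect_equal(interflow_nitrogen_flux(100, NA_real_, beta = 0.4), 0)
  # identity with (1 - beta) Q_s N / V_s
  v_s <- 1e5
  q_s <- 2e3
  expect_equal(
    interflow_nitrogen_flux(50, v_s / q_s, 0.4),
    (1 - 0.4) * q_s * 50 / v_s
  )

  expect_equal(groundwater_exchange_flux(1000, 100, 20, 1000, 0), 0)
  expect_equal(groundwater_exchange_flux(1000, 100, 20, 1000, 5), 10)
  expect_equal(groundwater_exchange_flux(1000, NA, 20, 1000, -50), -1)

  expect_equal(
    vadose_groundwater_nitrogen_flux(50, 1e5, 0, 1e6, 2000, 0.5), 0.5
  )
  expect_equal(
    vadose_groundwater_nitrogen_flux(50, 1e5, 100, 1e6, -1000, 0.5), -0.1
  )
  expect_equal(
    vadose_groundwater_nitrogen_flux(50, 1e5, 100, 1e6, 0, 0.5), 0
  )
})

test_that("in-stream and groundwater rates are temperature corrected", {
  expect_equal(temperature_corrected_stream_rate(1.5, 20), 1.5)
  expect_rel_equal(
    temperature_corrected_stream_rate(1.5, 10),
    1.5 * 1.07^-10, tol = 1e-12
  )
  expect_lt(abs(temperature_corrected_stream_rate(1.5, 10) - 0.7625), 1e-4)
  grid <- seq(0, 30, by = 1)
  expect_true(
    all(diff(temperature_corrected_stream_rate(1, grid)) > 0)
  )

  gp <- gw_denit_params(k_den_max = 0.001)
  expect_equal(groundwater_denit_rate(gp, 3.8, 2e5), 0.001)
  expect_equal(groundwater_denit_rate(gp, 3.8, 5e4), 0)
  expect_rel_equal(
    groundwater_denit_rate(gp, 0.8, 2e5), 0.001 * 0.3^3, tol = 1e-12
  )
})
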