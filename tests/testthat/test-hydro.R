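test_that("vadose outflow inverts the storage balance", {
  # flat storage, no infiltration: no flow
  expect_equal(back_calculate_soil_flow(c(100, 100, 100), rep(0, 3)),
    c(0, 0))
  # flat storage with 100 m^3/hr in: all of it flows out
  expect_equal(
    back_calculate_soil_flow(c(100, 100), c(100, 100)), 100
  )
  # no input, storage drops 50 m^3 over the hour: 50 m^3/hr released
  expect_equal(back_calculate_soil_flow(c(500, 450), c(0, 0)), 50)
})

test_that("groundwater balance partitions recharge by the baseflow index", {
  expect_equal(groundwater_balance(c(10, 10), q_s = 0, beta = 0.5), 0)
  expect_equal(groundwater_balance(c(10, 10), q_s = 1000, beta = 0.5), 500)
  # vadose gaining 200 m^3/hr, all drawn from groundwater storage
  expect_equal(groundwater_balance(c(1000, 800), q_s = -200, beta = 0.5), 0)
})

test_that("stream balance closes and floors negative discharge", {
  q <- stream_balance_discharge(
    v_r = c(10, 10), q_s = 0, q_g = 100, qq_m3_hr = c(20, 20),
    upstream = 0, beta = 0.5
  )
  expect_equal(as.numeric(q), 120)
  expect_equal(attr(q, "floored_deficit"), 0)
  q2 <- stream_balance_discharge(
    v_r = c(10, 10), q_s = 0, q_g = -50, qq_m3_hr = c(0, 0),
    upstream = 0, beta = 0.5
  )
  expect_equal(as.numeric(q2), 0)
  expect_equal(attr(q2, "floored_deficit"), 50)
})

test_that("residence times follow tau = V/Q with undefined markers", {
  expect_equal(residence_time(1000, 100), 10)
  expect_true(is.na(residence_time(1000, 0)))
  expect_true(is.na(residence_time(1000, -5)))
  expect_equal(residence_time(1000, 200), residence_time(1000, 100) / 2)
})

test_that("temperature transfer functions behave", {
  expect_equal(stream_temperature(c(-20, 0, 10), a = 4, b = 0), c(4, 4, 4))
  expect_equal(stream_temperature(-10, a = 0, b = 1), 0)
  grid <- seq(-20, 30, by = 0.5)
  expect_true(all(diff(stream_temperature(grid)) >= 0))
  f <- constant_forcing(two_basin_descriptors(), hours = 3)
  f$T_soil_C <- rep(c(0, 10), 3) # per-timestep means over {0, 10}
  expect_equal(groundwater_temperature(f)$T_gw_C, rep(5, 3))
})

test_that("routing accumulates upstream discharge at the confluence", {
  d <- two_basin_descriptors()
  # steady storages; 'up' receives groundwater discharge only via q_g = 0,
  # so drive flow with overland input in both basins
  f <- constant_forcing(d, hours = 24, qq_m3_hr = 10)
  h <- derive_hydro_fluxes(f, d, quiet = TRUE)
  up <- dplyr::filter(h, subwatershed == "up")
  dn <- dplyr::filter(h, subwatershed == "dn")
  expect_equal(up$Q_r_m3_day, rep(240, 23))
  # downstream outlet carries local 240 plus upstream 240
  expect_equal(dn$Q_r_m3_day, rep(480, 23))
  expect_equal(dn$upstream_m3_day, up$Q_r_m3_day)
})

test_that("re-integrating back-calculated flows reproduces the volumes", {
  d <- two_basin_descriptors()
  f <- generate_forcing(forcing_config(seed = 4, n_years = 1), d)
  h <- derive_hydro_fluxes(f, d, quiet = TRUE)
  for (id in d$id) {
    fi <- dplyr::filter(f, subwatershed == id)
    hi <- dplyr::filter(h, subwatershed == id)
    # vadose: V(t+1) = V(t) + (infilt - Q_s) dt
    v_s <- fi$V_s_m3[1] +
      cumsum(hi$infilt_m3_day / 24 - hi$Q_s_m3_day / 24)
    expect_lt(
      max(abs(v_s - fi$V_s_m3[-1]) / fi$V_s_m3[-1]), 1e-6
    )
    # groundwater: V(t+1) = V(t) + (recharge - Q_g) dt
    rech <- ifelse(hi$Q_s_m3_day > 0, hi$beta * hi$Q_s_m3_day,
      hi$Q_s_m3_day)
    v_g <- fi$V_g_m3[1] + cumsum((rech - hi$Q_g_m3_day) / 24)
    expect_lt(max(abs(v_g - fi$V_g_m3[-1]) / fi$V_g_m3[-1]), 1e-6)
    # stream: V(t+1) = V(t) + (inflow - Q_r) dt
    inflow <- (1 - hi$beta) * pmax(hi$Q_s_m3_day, 0) + hi$Q_g_m3_day +
      hi$qq_m3_day + hi$upstream_m3_day
    v_r <- fi$V_r_m3[1] + cumsum((inflow - hi$Q_r_m3_day) / 24)
    expect_lt(max(abs(v_r - fi$V_r_m3[-1]) / fi$V_r_m3[-1]), 1e-6)
  }
})

test_that("watershed-total stream balance is conserved through routing", {
  f <- generate_forcing(forcing_config(seed = 9, n_years = 1))
  h <- derive_hydro_fluxes(f, quiet = TRUE)
  expect_equal(sum(h$floored_deficit_m3_hr), 0)
  per_step <- h |>
    dplyr::group_by(timestamp) |>
    dplyr::summarise(
      local = sum((1 - beta) * pmax(Q_s_m3_day, 0) + Q_g_m3_day +
        qq_m3_day),
      outlet = sum(Q_r_m3_day[subwatershed == "LT"]),
      .groups = "drop"
    )
  # identity: outlet discharge = local inputs - total stream dV/dt
  f_sorted <- dplyr::arrange(f, subwatershed, timestamp)
  tot_dv <- f_sorted |>
    dplyr::group_by(subwatershed) |>
    dplyr::reframe(
      timestamp = timestamp[-dplyr::n()],
      dv_day = diff(V_r_m3) * 24
    ) |>
    dplyr::group_by(timestamp) |>
    dplyr::summarise(dv_day = sum(dv_day), .groups = "drop")
  chk <- dplyr::left_join(per_step, tot_dv, by = "timestamp")
  expect_lt(
    max(abs(chk$outlet - (chk$local - chk$dv_day)) /
      pmax(abs(chk$outlet), 1)), 1e-6
  )
})
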