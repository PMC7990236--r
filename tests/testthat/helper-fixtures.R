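# Small fixtures built in code: a two-basin routed toy watershed, a
# single-basin unit catchment, and constant (steady) forcing for
# closed-form comparisons.

two_basin_descriptors <- function() {
  tibble::tibble(
    id = c("up", "dn"),
    area_m2 = c(1e6, 2e6),
    frac_deciduous = c(0.2, 0.1),
    frac_coniferous = c(0.3, 0.2),
    frac_meadow = c(0.3, 0.5),
    frac_willow = c(0.1, 0.1),
    mancos_fraction = c(0.5, 0.2),
    downstream_id = c("dn", NA)
  )
}

one_basin_descriptors <- function(frac_meadow = 1, area_m2 = 1e6,
                                  mancos_fraction = 1) {
  tibble::tibble(
    id = "X",
    area_m2 = area_m2,
    frac_deciduous = 0,
    frac_coniferous = 0,
    frac_meadow = frac_meadow,
    frac_willow = 0,
    mancos_fraction = mancos_fraction,
    downstream_id = NA_character_
  )
}

# Steady forcing: constant storages (so all back-calculated flows are
# zero unless infilt/qq are supplied), constant temperatures.
constant_forcing <- function(descriptors, hours = 48,
                             origin = "2014-10-01",
                             v_s = 1e5, v_g = 1e6, v_r = 1e4,
                             infilt_m3_hr = 0, qq_m3_hr = 0,
                             t_soil = 5, t_air = 10) {
  ts <- seq(
    lubridate::as_datetime(origin, tz = "UTC"),
    by = "hour", length.out = hours
  )
  tidyr::crossing(
    timestamp = ts,
    subwatershed = descriptors$id
  ) |>
    dplyr::mutate(
      V_s_m3 = v_s, V_g_m3 = v_g, V_r_m3 = v_r,
      infilt_minus_ets_m3_per_hr = infilt_m3_hr,
      qq_minus_etr_m3_per_hr = qq_m3_hr,
      T_soil_C = t_soil, T_air_C = t_air
    )
}

# A minimal fake simulation object whose ledger holds prescribed
# constant fluxes (mol day^-1) over a given number of daily steps, for
# exercising budget arithmetic independently of the integrator.
fake_sim <- function(fluxes, days = 365, id = "X",
                     origin = "2014-10-01") {
  kinds <- riverN:::LEDGER_KINDS
  cols <- riverN:::ledger_col_names()
  n_steps <- days * 24
  led <- array(0, c(n_steps, 1, length(cols)),
    dimnames = list(NULL, id, cols)
  )
  for (nm in names(fluxes)) {
    led[, 1, nm] <- fluxes[[nm]]
  }
  ts <- seq(
    lubridate::as_datetime(origin, tz = "UTC"),
    by = "hour", length.out = n_steps
  )
  structure(
    list(
      states = array(0, c(n_steps + 1, 1, 9),
        dimnames = list(NULL, id, riverN:::POOL_NAMES)
      ),
      ledger = led,
      timestamps = ts,
      ids = id,
      descriptors = one_basin_descriptors(),
      scenario = list(name = "fake"),
      dt_day = 1 / 24,
      log = list(n_limited = 0, n_nonneg = 0)
    ),
    class = "watershed_sim"
  )
}

# A reaction-free scenario with selected pieces switched back on.
tracer_with <- function(...) {
  s <- tracer_scenario()
  mods <- list(...)
  for (nm in names(mods)) s[[nm]] <- mods[[nm]]
  s
}

expect_rel_equal <- function(actual, expected, tol = 1e-8) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
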