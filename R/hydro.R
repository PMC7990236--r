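#' Back-calculate vadose-zone outflow from the storage series
#'
#' Inverts the vadose water balance
#' `dV_s/dt = [Infilt - ET_s] - Q_s`: the soil-water flow exiting (positive)
#' or entering (negative) the vadose zone over each hourly step is the net
#' infiltration minus the observed storage change.
#'
#' @param v_s Hourly vadose storage series (m^3).
#' @param infilt_m3_hr Net infiltration minus soil ET (m^3 hr^-1, signed).
#' @return Numeric vector of `Q_s` in m^3 hr^-1, one element shorter than
#'   the input (the final step has no successor storage).
#' @export
back_calculate_soil_flow <- function(v_s, infilt_m3_hr) {
  n <- length(v_s)
  stopifnot(length(infilt_m3_hr) == n, n >= 2)
  infilt_m3_hr[-n] - diff(v_s)
}

#' Groundwater balance: flow from groundwater to the stream
#'
#' When the vadose zone is draining (`Q_s > 0`) a fraction `beta` of that
#' flow recharges groundwater; when it is gaining (`Q_s <= 0`) the deficit
#' is drawn entirely from groundwater. The groundwater-to-stream flow
#' `Q_g` (negative = stream recharging groundwater) is the recharge minus
#' the observed groundwater storage change.
#'
#' @param v_g Hourly groundwater storage series (m^3).
#' @param q_s Vadose outflow per step (m^3 hr^-1, signed), length
#'   `length(v_g) - 1`.
#' @param beta Baseflow index per step (same length as `q_s`).
#' @return `Q_g` in m^3 hr^-1, signed.
#' @export
groundwater_balance <- function(v_g, q_s, beta) {
  n <- length(v_g)
  stopifnot(length(q_s) == n - 1, length(beta) == n - 1)
  recharge <- ifelse(q_s > 0, beta * q_s, q_s)
  recharge - diff(v_g)
}

#' Stream balance: discharge at the sub-watershed outlet
#'
#' Closes the stream water balance: outlet discharge is interflow
#' (`(1 - beta)` share of positive vadose outflow) plus groundwater
#' discharge, overland flow and upstream inflow, minus the observed stream
#' storage change. Negative balances are floored at zero and the deficit
#' reported via an attribute.
#'
#' @param v_r Hourly stream storage series (m^3).
#' @param q_s,q_g Per-step vadose and groundwater flows (m^3 hr^-1).
#' @param qq_m3_hr Overland flow minus stream ET (m^3 hr^-1, signed).
#' @param upstream Per-step sum of upstream outlet discharges (m^3 hr^-1).
#' @param beta Baseflow index per step.
#' @return `Q_r` in m^3 hr^-1 (non-negative), with attribute
#'   `"floored_deficit"` holding the total flow deficit removed by
#'   flooring (m^3 hr^-1 summed over steps).
#' @export
stream_balance_discharge <- function(v_r, q_s, q_g, qq_m3_hr, upstream,
                                     beta) {
  n <- length(v_r)
  stopifnot(
    length(q_s) == n - 1, length(q_g) == n - 1,
    length(beta) == n - 1, length(upstream) == n - 1
  )
  q_r <- (1 - beta) * pmax(q_s, 0) + q_g + qq_m3_hr[-n] + upstream -
    diff(v_r)
  deficit <- sum(pmin(q_r, 0))
  structure(pmax(q_r, 0), floored_deficit = -deficit)
}

#' Residence time of a compartment
#'
#' `tau = V / Q` in days whenever the outflow is positive; `NA` (an
#' undefined marker, not zero) otherwise.
#'
#' @param v Storage (m^3).
#' @param q_m3_day Outflow (m^3 day^-1, signed).
#' @return Residence time in days, `NA` where `q <= 0`.
#' @export
residence_time <- function(v, q_m3_day) {
  ifelse(q_m3_day > 0, v / q_m3_day, NA_real_)
}

#' Empirical stream temperature from air temperature
#'
#' Affine air-to-water temperature transfer `T_water = a + b * T_air`,
#' floored at 0 degrees C. The default coefficients (`a = 3.5`,
#' `b = 0.62`) are a literature-derived stand-in in the range typical of
#' published air--water regressions for cold streams, not a site-calibrated
#' relationship; override them where a local regression is available.
#'
#' @param t_air_C Air temperature (degrees C).
#' @param a,b Intercept and slope of the affine map.
#' @return Water temperature (degrees C), non-negative.
#' @export
stream_temperature <- function(t_air_C, a = 3.5, b = 0.62) {
  pmax(0, a + b * t_air_C)
}

#' Watershed-wide groundwater temperature
#'
#' The arithmetic mean of all sub-watersheds' soil temperatures at each
#' timestep, used as a single groundwater temperature for the watershed.
#'
#' @param forcing A validated forcing tibble.
#' @return A tibble with columns `timestamp` and `T_gw_C`.
#' @export
groundwater_temperature <- function(forcing) {
  forcing %>%
    group_by(.data$timestamp) %>%
    summarise(T_gw_C = mean(.data$T_soil_C), .groups = "drop")
}

#' Derive the hydrologic flux series that drive the nitrogen model
#'
#' Back-calculates, for every sub-watershed and hourly step, the
#' inter-compartment water flows (vadose outflow `Q_s`, groundwater
#' exchange `Q_g`, outlet discharge `Q_r`), the active baseflow index, the
#' residence times of all three compartments, and the water/groundwater
#' temperatures. Flows are converted to the model's canonical m^3 day^-1;
#' the series is one hour shorter than the forcing (the last step has no
#' successor storages; a notice reports the truncation).
#'
#' Sub-watersheds are processed in topological order so each reach
#' receives the resolved discharge of its upstream neighbours.
#'
#' @param forcing A forcing tibble (validated internally).
#' @param descriptors Sub-watershed descriptor table.
#' @param baseflow Baseflow schedule tibble.
#' @param stream_temp_a,stream_temp_b Coefficients passed to
#'   [stream_temperature()].
#' @param quiet Suppress the truncation notice.
#' @return A tibble with one row per (timestamp, sub-watershed) holding the
#'   forcing states plus `Q_s_m3_day`, `Q_g_m3_day`, `Q_r_m3_day`, `beta`,
#'   `tau_s_day`, `tau_g_day`, `tau_r_day`, `T_water_C`, `T_gw_C`, and
#'   `infilt_m3_day` / `qq_m3_day` (the forcing fluxes in day units).
#' @examples
#' f <- generate_forcing(forcing_config(seed = 1, n_years = 1))
#' h <- derive_hydro_fluxes(f, quiet = TRUE)
#' @export
derive_hydro_fluxes <- function(forcing,
                                descriptors = east_river_subwatersheds(),
                                baseflow = default_baseflow_schedule(descriptors),
                                stream_temp_a = 3.5,
                                stream_temp_b = 0.62,
                                quiet = FALSE) {
  forcing <- validate_forcing(forcing, descriptors)
  t_gw <- groundwater_temperature(forcing)
  ids <- topological_order(descriptors)
  n_ts <- length(unique(forcing$timestamp))
  if (n_ts < 2) abort("forcing must contain at least two timestamps")
  if (!quiet) {
    inform(paste0(
      "hydro flux series truncated to ", n_ts - 1,
      " steps (final forcing row has no successor)"
    ))
  }

  q_r_day <- list()
  out <- list()
  for (id in ids) {
    fi <- forcing[forcing$subwatershed == id, ]
    ts <- fi$timestamp[-nrow(fi)]
    doy <- lubridate::yday(ts)
    beta <- beta_at(baseflow, id, doy)

    q_s_hr <- back_calculate_soil_flow(fi$V_s_m3, fi$infilt_minus_ets_m3_per_hr)
    q_g_hr <- groundwater_balance(fi$V_g_m3, q_s_hr, beta)
    upstream_hr <- Reduce(`+`, q_r_day[
      descriptors$id[!is.na(descriptors$downstream_id) &
        descriptors$downstream_id == id]
    ], accumulate = FALSE) %||% rep(0, length(q_s_hr))
    upstream_hr <- upstream_hr / 24
    q_r_hr <- stream_balance_discharge(
      fi$V_r_m3, q_s_hr, q_g_hr, fi$qq_minus_etr_m3_per_hr,
      upstream_hr, beta
    )
    q_r_day[[id]] <- as.numeric(q_r_hr) * 24

    keep <- seq_len(nrow(fi) - 1)
    out[[id]] <- tibble(
      timestamp = ts,
      subwatershed = id,
      V_s_m3 = fi$V_s_m3[keep],
      V_g_m3 = fi$V_g_m3[keep],
      V_r_m3 = fi$V_r_m3[keep],
      infilt_m3_day = fi$infilt_minus_ets_m3_per_hr[keep] * 24,
      qq_m3_day = fi$qq_minus_etr_m3_per_hr[keep] * 24,
      T_soil_C = fi$T_soil_C[keep],
      T_air_C = fi$T_air_C[keep],
      Q_s_m3_day = q_s_hr * 24,
      Q_g_m3_day = q_g_hr * 24,
      Q_r_m3_day = as.numeric(q_r_hr) * 24,
      upstream_m3_day = upstream_hr * 24,
      beta = beta,
      floored_deficit_m3_hr = attr(q_r_hr, "floored_deficit")
    ) %>%
      mutate(
        tau_s_day = residence_time(.data$V_s_m3, .data$Q_s_m3_day),
        tau_g_day = residence_time(.data$V_g_m3, .data$Q_g_m3_day),
        tau_r_day = residence_time(.data$V_r_m3, .data$Q_r_m3_day),
        T_water_C = stream_temperature(
          .data$T_air_C,
          a = stream_temp_a, b = stream_temp_b
        )
      )
  }
  bind_rows(out[descriptors$id]) %>%
    left_join(t_gw, by = "timestamp") %>%
    arrange(.data$timestamp, .data$subwatershed)
}
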