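#' Soil temperature correction factor
#'
#' `alpha = theta_s^((T_soil - 5) / 2)`, the unitless multiplier applied
#' to vadose-zone biological rates and maximum uptake fluxes. With the
#' default base of 12 the factor grows extremely fast above the 5 degree C
#' reference; a warning fires when it exceeds 1e6.
#'
#' @param t_soil_C Soil temperature (degrees C).
#' @param theta_s Base of the exponential response (default 12).
#' @return Unitless factor, 1 at 5 degrees C.
#' @examples
#' soil_temperature_factor(5) # 1
#' soil_temperature_factor(7) # 12
#' @export
soil_temperature_factor <- function(t_soil_C, theta_s = 12) {
  alpha <- theta_s^((t_soil_C - 5) / 2)
  if (any(alpha > 1e6)) {
    warn("soil temperature factor exceeds 1e6; vadose rates will be extreme")
  }
  alpha
}

#' Land-cover-weighted vadose rate constant
#'
#' Effective sub-watershed rate constant: the cover-fraction-weighted sum
#' of per-cover rate constants, scaled by the soil temperature factor.
#' Barren/developed area (the remainder of the cover fractions) carries a
#' zero rate. The result is a first-order constant in day^-1; no area
#' factor enters (a rate constant times area would not be a rate).
#'
#' @param k_cover Named numeric of per-cover constants (day^-1) over
#'   `df`, `cf`, `ms`, `ww`.
#' @param descriptor One-row descriptor tibble.
#' @param alpha Soil temperature factor.
#' @return Effective rate constant (day^-1).
#' @export
landcover_weighted_rate <- function(k_cover, descriptor, alpha = 1) {
  alpha * (
    k_cover[["df"]] * descriptor$frac_deciduous +
      k_cover[["cf"]] * descriptor$frac_coniferous +
      k_cover[["ms"]] * descriptor$frac_meadow +
      k_cover[["ww"]] * descriptor$frac_willow
  )
}

#' Maximum plant uptake flux for a sub-watershed
#'
#' `F_max = alpha * A * sum_c(F_max_c * rho_c)` in mol day^-1: the
#' cover-weighted areal maximum uptake scaled by sub-watershed area and
#' the soil temperature factor.
#'
#' @param descriptor One-row descriptor tibble.
#' @param uptake An [uptake_params()] object.
#' @param alpha Soil temperature factor.
#' @param species One of `"a"`, `"n"`, `"o"`.
#' @return Maximum uptake flux (mol day^-1).
#' @export
max_uptake_flux <- function(descriptor, uptake, alpha, species) {
  fm <- uptake$f_max[, species]
  alpha * descriptor$area_m2 * (
    fm[["df"]] * descriptor$frac_deciduous +
      fm[["cf"]] * descriptor$frac_coniferous +
      fm[["ms"]] * descriptor$frac_meadow +
      fm[["ww"]] * descriptor$frac_willow
  )
}

#' Monod (saturating) uptake flux
#'
#' `F = F_max * N / (K_m * V_s + N)`: uptake saturates at `F_max` as the
#' pool grows and is half-maximal when the vadose concentration equals
#' `K_m`.
#'
#' @param n_mol Vadose pool of the species (mol, >= 0).
#' @param v_s_m3 Vadose water volume (m^3, > 0).
#' @param f_max Maximum uptake flux (mol day^-1).
#' @param K_m Half-saturation constant (mol m^-3).
#' @return Uptake flux (mol day^-1), strictly below `f_max` for finite
#'   pools.
#' @export
monod_uptake_flux <- function(n_mol, v_s_m3, f_max, K_m) {
  if (any(v_s_m3 <= 0)) abort("vadose volume must be positive")
  f_max * n_mol / (K_m * v_s_m3 + n_mol)
}

#' Atmospheric deposition fluxes
#'
#' Wet deposition is precipitation concentration times the net water flux
#' into the compartment (`[Infilt - ET_s]` for the vadose zone,
#' `[Q_q - ET_r]` for the stream), applied with its sign unless the
#' parameter set requests clamping at zero. Dry deposition is the areal
#' rate times sub-watershed area and reaches the vadose zone only.
#'
#' @param deposition A [deposition_params()] object.
#' @param descriptor One-row descriptor tibble.
#' @param water_flux_m3_day Net water flux (m^3 day^-1, signed).
#' @param target `"vadose"` or `"stream"`.
#' @return Named list with per-species `wet` and `dry` fluxes
#'   (mol day^-1; `dry` is zero for the stream).
#' @export
deposition_fluxes <- function(deposition, descriptor, water_flux_m3_day,
                              target = c("vadose", "stream")) {
  target <- match.arg(target)
  wf <- if (deposition$clamp_wet_deposition) {
    pmax(water_flux_m3_day, 0)
  } else {
    water_flux_m3_day
  }
  wet <- deposition$wet * wf
  dry <- if (target == "vadose") {
    deposition$dry * descriptor$area_m2
  } else {
    c(a = 0, n = 0, o = 0)
  }
  list(wet = wet, dry = dry)
}

#' Shale weathering fluxes to the vadose zone and groundwater
#'
#' The vadose (saprolite) share is scaled by the sub-watershed's shale
#' fraction; the groundwater (fractured bedrock) share uses the full area
#' by default. Both are constant in time.
#'
#' @param weathering A [weathering_params()] object.
#' @param descriptor One-row descriptor tibble.
#' @return List with per-species numeric vectors `vadose` and
#'   `groundwater` (mol day^-1).
#' @export
weathering_fluxes <- function(weathering, descriptor) {
  gw_area <- if (weathering$groundwater_area_mode == "full_area") {
    descriptor$area_m2
  } else {
    descriptor$mancos_fraction * descriptor$area_m2
  }
  list(
    vadose = weathering$vadose_share * weathering$M *
      descriptor$mancos_fraction * descriptor$area_m2,
    groundwater = weathering$groundwater_share * weathering$M * gw_area
  )
}

#' Biological fixation flux
#'
#' A uniform areal rate draw applied to the nitrogen-fixer area (the
#' fixer fraction of meadow cover), gated on soil temperature above
#' freezing. The draw is supplied by the caller (the simulator draws once
#' per sub-watershed per day).
#'
#' @param fixation A [fixation_params()] object.
#' @param descriptor One-row descriptor tibble.
#' @param t_soil_C Soil temperature (degrees C).
#' @param areal_draw Uniform draw(s) in
#'   `[fixation$lower, fixation$upper]` (mol m^-2 day^-1); if `NULL`, a
#'   draw is taken from the current RNG stream.
#' @return Ammonium fixation flux (mol day^-1).
#' @export
fixation_flux <- function(fixation, descriptor, t_soil_C,
                          areal_draw = NULL) {
  if (is.null(areal_draw)) {
    areal_draw <- runif(length(t_soil_C), fixation$lower, fixation$upper)
  }
  fixer_area <- fixation$fixer_fraction * descriptor$frac_meadow *
    descriptor$area_m2
  ifelse(t_soil_C > 0, areal_draw * fixer_area, 0)
}

#' Spruce gross primary productivity from air temperature
#'
#' `GPP = c1 / (c2 + exp(-c3 * T_air))` in mg C m^-2 day^-1, saturating
#' at `c1 / c2` for warm air.
#'
#' @param t_air_C Air temperature (degrees C).
#' @param coef Coefficients `(c1, c2, c3)`.
#' @return GPP (mg C m^-2 day^-1).
#' @export
gpp_spruce <- function(t_air_C, coef = c(1.51, 0.2375, 0.21)) {
  coef[1] / (coef[2] + exp(-coef[3] * t_air_C))
}

#' Litterfall DON flux for a sub-watershed
#'
#' Sums the piecewise-constant deciduous, meadow and willow interval
#' rates (g N m^-2 day^-1, optionally jittered) times their cover areas,
#' plus the GPP-driven spruce contribution
#' `upsilon * 0.0057 * exp(-0.293 * GPP)` over coniferous cover,
#' converted to mol day^-1 at 14 g N mol^-1. Day-of-year intervals are
#' leap-aware (the third interval runs to day 366 in leap years).
#'
#' @param litter A [litter_params()] object.
#' @param descriptor One-row descriptor tibble.
#' @param doy Day of year (vectorized).
#' @param t_air_C Air temperature (degrees C, vectorized).
#' @param jitter_draw Optional multiplicative jitter factor(s); drawn
#'   from U(0.5, 1.5) when jitter mode is on and no draw is supplied.
#' @return DON litter flux (mol day^-1).
#' @export
litter_flux <- function(litter, descriptor, doy, t_air_C,
                        jitter_draw = NULL) {
  interval3 <- findInterval(doy, c(1, 151, 251)) # 1, 2, 3
  rate_df <- litter$deciduous[interval3]
  rate_ww <- litter$willow[interval3]
  rate_ms <- ifelse(doy < 200, litter$meadow[1], litter$meadow[2])
  jf <- if (litter$jitter == "uniform_multiplicative") {
    jitter_draw %||% runif(length(doy), 0.5, 1.5)
  } else {
    1
  }
  gpp <- gpp_spruce(t_air_C, litter$gpp_coef)
  rate_cf <- litter$upsilon * litter$litter_coef[1] *
    exp(litter$litter_coef[2] * gpp)
  g_per_day <- descriptor$area_m2 * (
    jf * rate_df * descriptor$frac_deciduous +
      jf * rate_ms * descriptor$frac_meadow +
      jf * rate_ww * descriptor$frac_willow +
      rate_cf * descriptor$frac_coniferous
  )
  g_per_day / N_MOLAR_MASS
}

#' Cattle DON flux for a sub-watershed and day of year
#'
#' @param cattle A [cattle_params()] object.
#' @param id Sub-watershed id.
#' @param doy Day of year (vectorized).
#' @return DON flux (mol day^-1).
#' @export
cattle_don_flux <- function(cattle, id, doy) {
  sched <- cattle$schedule[cattle$schedule$id == id, ]
  G <- rep(0, length(doy))
  for (k in seq_len(nrow(sched))) {
    hit <- doy >= sched$start_doy[k] & doy <= sched$end_doy[k]
    G[hit] <- sched$G[k]
  }
  cattle$n_cows * G * (cattle$L_dung + cattle$L_urine)
}

#' Interflow nitrogen flux to the stream
#'
#' `F = (1 - beta) * N / tau_s` when the vadose zone is draining
#' (`tau_s` defined); zero otherwise. Equivalent to
#' `(1 - beta) * Q_s * N / V_s`.
#'
#' @param n_mol Vadose pool (mol).
#' @param tau_s_day Vadose residence time (days, `NA` when `Q_s <= 0`).
#' @param beta Baseflow index.
#' @return Interflow flux (mol day^-1).
#' @export
interflow_nitrogen_flux <- function(n_mol, tau_s_day, beta) {
  ifelse(is.na(tau_s_day), 0, (1 - beta) * n_mol / tau_s_day)
}

#' Groundwater--stream nitrogen exchange
#'
#' Discharging groundwater (`Q_g > 0`) delivers `N_g / tau_g` to the
#' stream; a recharging stream (`Q_g < 0`) loses water at stream
#' concentration, `(N_r / V_r) * Q_g` (negative = stream to groundwater).
#'
#' @param n_g_mol Groundwater pool (mol).
#' @param tau_g_day Groundwater residence time (days, `NA` when
#'   `Q_g <= 0`).
#' @param n_r_mol Stream pool (mol).
#' @param v_r_m3 Stream volume (m^3, > 0).
#' @param q_g_m3_day Groundwater-to-stream flow (m^3 day^-1, signed).
#' @return Exchange flux (mol day^-1, signed; positive = to stream).
#' @export
groundwater_exchange_flux <- function(n_g_mol, tau_g_day, n_r_mol, v_r_m3,
                                      q_g_m3_day) {
  if (any(v_r_m3 <= 0)) abort("stream volume must be positive")
  dplyr::case_when(
    q_g_m3_day > 0 ~ n_g_mol / tau_g_day,
    q_g_m3_day < 0 ~ (n_r_mol / v_r_m3) * q_g_m3_day,
    .default = 0
  )
}

#' Temperature-corrected in-stream rate constant
#'
#' `k = k_20 * theta_r^(T_water - 20)`.
#'
#' @param k20 Rate constant at 20 degrees C (day^-1).
#' @param t_water_C Water temperature (degrees C).
#' @param theta_r Temperature base (default 1.07).
#' @return Rate constant at `t_water_C` (day^-1).
#' @export
temperature_corrected_stream_rate <- function(k20, t_water_C,
                                              theta_r = 1.07) {
  k20 * theta_r^(t_water_C - 20)
}

#' Vadose--groundwater nitrogen transfer
#'
#' `F = beta * Q_s * N_s / V_s` when the vadose zone drains to
#' groundwater (`Q_s > 0`); `F = Q_s * N_g / V_g` (negative, groundwater
#' to vadose) when flow reverses; zero at `Q_s = 0`.
#'
#' @param n_s_mol Vadose pool (mol).
#' @param v_s_m3 Vadose volume (m^3, > 0).
#' @param n_g_mol Groundwater pool (mol).
#' @param v_g_m3 Groundwater volume (m^3, > 0).
#' @param q_s_m3_day Vadose outflow (m^3 day^-1, signed).
#' @param beta Baseflow index.
#' @return Transfer flux (mol day^-1, signed; positive = to groundwater).
#' @export
vadose_groundwater_nitrogen_flux <- function(n_s_mol, v_s_m3, n_g_mol,
                                             v_g_m3, q_s_m3_day, beta) {
  if (any(v_s_m3 <= 0) || any(v_g_m3 <= 0)) {
    abort("vadose and groundwater volumes must be positive")
  }
  dplyr::case_when(
    q_s_m3_day > 0 ~ beta * q_s_m3_day * n_s_mol / v_s_m3,
    q_s_m3_day < 0 ~ q_s_m3_day * n_g_mol / v_g_m3,
    .default = 0
  )
}

#' Groundwater denitrification rate constant
#'
#' `k = k_den_max * theta_g^(T_ref - T_gw)` when the sub-watershed's
#' vadose outflow exceeds the activation threshold (rapid recharge), zero
#' otherwise.
#'
#' @param params A [gw_denit_params()] object.
#' @param t_gw_C Groundwater temperature (degrees C).
#' @param q_s_m3_day Vadose outflow (m^3 day^-1).
#' @return Rate constant (day^-1).
#' @export
groundwater_denit_rate <- function(params, t_gw_C, q_s_m3_day) {
  ifelse(
    q_s_m3_day > params$q_s_threshold,
    params$k_den_max * params$theta_g^(params$T_ref - t_gw_C),
    0
  )
}
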