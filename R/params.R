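#' Wet-deposition DON concentration from the 25%-of-TDN rule
#'
#' Dissolved organic nitrogen in precipitation is assumed to make up 25%
#' of total dissolved nitrogen. Given the measured nitrate and ammonium
#' concentrations `n` and `a`, TDN = n + a + DON and DON = 0.25 * TDN,
#' hence DON = (n + a) / 3.
#'
#' @param nitrate,ammonium Wet-deposition concentrations (mol m^-3).
#' @return DON concentration (mol m^-3).
#' @examples
#' don_from_tdn_rule(0.011, 0.0068)
#' @export
don_from_tdn_rule <- function(nitrate, ammonium) {
  (nitrate + ammonium) / 3
}

#' Atmospheric deposition parameters
#'
#' Wet deposition is parameterized as constant precipitation
#' concentrations (mol m^-3) multiplied by the net water flux entering a
#' compartment; dry deposition as constant areal rates (mol m^-2 day^-1)
#' applied to the vadose zone. Defaults: long-term mean wet concentrations
#' of 0.011 mol m^-3 nitrate and 0.0068 mol m^-3 ammonium from the
#' CASTNET-style monitoring record, wet DON from the 25%-of-TDN rule.
#'
#' The monitoring record's dry deposition is reported as 0.28 (nitrate),
#' 1.29 (ammonium) and 0.52 (DON, 25% rule) in its printed areal unit,
#' which is inconsistent by ~6 orders of magnitude with the corresponding
#' printed annual watershed totals (1.73e4, 7.99e4, 3.24e4 mol yr^-1 --
#' the NH4:NO3 ratios agree, indicating a constant unit slip). The
#' defaults are therefore rescaled so that the annual watershed totals are
#' reproduced over the default catchment area.
#'
#' @param wet_no3,wet_nh4 Wet concentrations (mol m^-3).
#' @param wet_don Wet DON concentration; default derived via
#'   [don_from_tdn_rule()].
#' @param dry_no3,dry_nh4,dry_don Dry areal rates (mol m^-2 day^-1).
#' @param clamp_wet_deposition If `TRUE`, the wet-deposition term is
#'   floored at zero when the net water flux is negative; by default the
#'   signed term is applied verbatim.
#' @param total_area_m2 Area used to rescale the printed dry totals.
#' @return A list of class `"deposition_params"`.
#' @export
deposition_params <- function(wet_no3 = 0.011,
                              wet_nh4 = 0.0068,
                              wet_don = don_from_tdn_rule(wet_no3, wet_nh4),
                              total_area_m2 = sum(east_river_subwatersheds()$area_m2),
                              dry_no3 = 1.73e4 / (total_area_m2 * 365),
                              dry_nh4 = 7.99e4 / (total_area_m2 * 365),
                              dry_don = 3.24e4 / (total_area_m2 * 365),
                              clamp_wet_deposition = FALSE) {
  p <- list(
    wet = c(a = wet_nh4, n = wet_no3, o = wet_don),
    dry = c(a = dry_nh4, n = dry_no3, o = dry_don),
    clamp_wet_deposition = clamp_wet_deposition
  )
  if (any(p$wet < 0) || any(p$dry < 0)) {
    abort("deposition concentrations and rates must be non-negative")
  }
  structure(p, class = "deposition_params")
}

#' Shale (Mancos) weathering parameters
#'
#' Constant areal fluxes of ammonium, nitrate and DON mobilized from
#' nitrogen-rich shale. By default 90% of the flux enters the vadose zone
#' (saprolite), scaled by each sub-watershed's shale fraction, and 10%
#' enters groundwater from fractured bedrock over the full sub-watershed
#' area (`groundwater_area_mode = "full_area"`); set
#' `groundwater_area_mode = "mancos_area"` to scale the groundwater share
#' by the shale fraction as well.
#'
#' @param M_a,M_n,M_o Areal weathering fluxes (mol m^-2 day^-1).
#' @param vadose_share,groundwater_share Partitioning of the flux; must
#'   sum to 1.
#' @param groundwater_area_mode `"full_area"` or `"mancos_area"`.
#' @return A list of class `"weathering_params"`.
#' @export
weathering_params <- function(M_a = 2.0e-7,
                              M_n = 7.5e-6,
                              M_o = 7.5e-6,
                              vadose_share = 0.9,
                              groundwater_share = 0.1,
                              groundwater_area_mode = c(
                                "full_area", "mancos_area"
                              )) {
  groundwater_area_mode <- match.arg(groundwater_area_mode)
  if (any(c(M_a, M_n, M_o) < 0)) abort("weathering rates must be >= 0")
  if (vadose_share < 0 || groundwater_share < 0 ||
    abs(vadose_share + groundwater_share - 1) > 1e-9) {
    abort("vadose_share and groundwater_share must be >= 0 and sum to 1")
  }
  structure(
    list(
      M = c(a = M_a, n = M_n, o = M_o),
      vadose_share = vadose_share,
      groundwater_share = groundwater_share,
      groundwater_area_mode = groundwater_area_mode
    ),
    class = "weathering_params"
  )
}

#' Plant uptake parameters (Monod kinetics)
#'
#' Maximum areal uptake fluxes per land cover and nitrogen species, and
#' half-saturation constants per species. The shipped defaults are
#' synthetic: literature-plausible magnitudes assembled from published
#' root-uptake rates and belowground-biomass compilations (the
#' site-specific table is not published); every value is overridable.
#'
#' @param f_max A 4 x 3 matrix (rows `df`, `cf`, `ms`, `ww` = deciduous,
#'   coniferous, meadow, willow; columns `a`, `n`, `o`) of maximum areal
#'   uptake fluxes (mol m^-2 day^-1).
#' @param K_m Named numeric of half-saturation constants per species
#'   (mol m^-3).
#' @param theta_s Base of the soil temperature correction factor.
#' @param msr Root mass per unit root area (g cm^-2); metadata only.
#' @return A list of class `"uptake_params"`.
#' @export
uptake_params <- function(f_max = rbind(
                            df = c(a = 2.5e-5, n = 2.0e-5, o = 1.0e-5),
                            cf = c(a = 1.5e-5, n = 1.2e-5, o = 8.0e-6),
                            ms = c(a = 2.0e-5, n = 1.8e-5, o = 6.0e-6),
                            ww = c(a = 3.0e-5, n = 2.5e-5, o = 1.2e-5)
                          ),
                          K_m = c(a = 0.02, n = 0.03, o = 0.01),
                          theta_s = 12,
                          msr = 0.0017) {
  if (any(f_max < 0) || any(K_m <= 0) || theta_s <= 0) {
    abort("uptake parameters must be positive")
  }
  stopifnot(
    identical(rownames(f_max), c("df", "cf", "ms", "ww")),
    identical(sort(names(K_m)), c("a", "n", "o"))
  )
  structure(
    list(f_max = f_max, K_m = K_m[c("a", "n", "o")], theta_s = theta_s,
      msr = msr),
    class = "uptake_params"
  )
}

#' Vadose-zone rate-constant table
#'
#' First-order rate constants (day^-1) for nitrification, net
#' mineralization and denitrification per land cover type. Effective
#' sub-watershed rates are the cover-fraction-weighted sums, scaled by the
#' soil temperature factor; see [landcover_weighted_rate()].
#'
#' @param k_nit,k_min,k_den Named numerics over covers `df`, `cf`, `ms`,
#'   `ww` (day^-1).
#' @return A tibble with columns `cover`, `k_nit`, `k_min`, `k_den`.
#' @export
vadose_rate_table <- function(k_nit = c(df = 0.05, cf = 0.05, ms = 0.05, ww = 0.09),
                              k_min = c(df = 0.2, cf = 0.2, ms = 0.15, ww = 0.7),
                              k_den = c(df = 0.001, cf = 0.001, ms = 0.001, ww = 0.001)) {
  covers <- c("df", "cf", "ms", "ww")
  if (any(c(k_nit, k_min, k_den) < 0)) abort("rate constants must be >= 0")
  tibble(
    cover = covers,
    k_nit = unname(k_nit[covers]),
    k_min = unname(k_min[covers]),
    k_den = unname(k_den[covers])
  )
}

#' In-stream rate parameters
#'
#' First-order in-stream rate constants at the 20 degree C reference
#' (day^-1) with an Arrhenius-style temperature correction base
#' `theta_r`. The net-mineralization constant defaults to 1.5 day^-1,
#' reflecting the fast breakdown of fresh terrestrial organic matter in
#' the water column; nitrification, in-stream uptake (primary
#' productivity) and denitrification are calibration parameters.
#'
#' @param k20_nit,k20_up,k20_den,k20_min Rate constants at 20 C (day^-1).
#' @param theta_r Temperature-correction base (default 1.07).
#' @return A list of class `"stream_rate_params"`.
#' @export
stream_rate_params <- function(k20_nit = 5.0,
                               k20_up = 2.0,
                               k20_den = 1.0,
                               k20_min = 1.5,
                               theta_r = 1.07) {
  if (any(c(k20_nit, k20_up, k20_den, k20_min) < 0) || theta_r <= 0) {
    abort("stream rate parameters must be non-negative (theta_r > 0)")
  }
  structure(
    list(
      k20 = c(nit = k20_nit, up = k20_up, den = k20_den, min = k20_min),
      theta_r = theta_r
    ),
    class = "stream_rate_params"
  )
}

#' Groundwater denitrification parameters
#'
#' Groundwater denitrification is restricted to periods of rapid recharge
#' (water-table rise and near-surface anoxia): the first-order rate is
#' `k_den_max * theta_g^(T_ref - T_gw)` when the vadose outflow of the
#' sub-watershed exceeds `q_s_threshold`, and zero otherwise. The
#' reference temperature is the maximum groundwater temperature
#' (3.8 degrees C).
#'
#' @param k_den_max Maximum denitrification reactivity (day^-1).
#' @param theta_g Temperature base (default 0.3).
#' @param T_ref Reference groundwater temperature (degrees C).
#' @param q_s_threshold Vadose-outflow activation threshold (m^3 day^-1).
#' @return A list of class `"gw_denit_params"`.
#' @export
gw_denit_params <- function(k_den_max = 0.001,
                            theta_g = 0.3,
                            T_ref = 3.8,
                            q_s_threshold = 1.0e5) {
  if (k_den_max < 0) abort("k_den_max must be >= 0")
  if (q_s_threshold <= 0) abort("q_s_threshold must be > 0")
  structure(
    list(
      k_den_max = k_den_max, theta_g = theta_g, T_ref = T_ref,
      q_s_threshold = q_s_threshold
    ),
    class = "gw_denit_params"
  )
}

#' Litterfall DON release parameters
#'
#' Deciduous, willow and meadow litter are piecewise-constant daily areal
#' DON release rates (g N m^-2 day^-1) over day-of-year intervals:
#' deciduous/willow use three intervals (days 1--150, 151--250, 251--end
#' of year, leap-aware), meadow two (before day 200, day 200 onward).
#' Coniferous (spruce) litter follows gross primary productivity:
#' `GPP = 1.51 / (0.2375 + exp(-0.21 * T_air))` (mg C m^-2 day^-1) and
#' `litter = upsilon * 0.0057 * exp(-0.293 * GPP)` (g N m^-2 day^-1),
#' with `upsilon` a unitless calibration scaling.
#'
#' Optional mean-preserving multiplicative jitter (uniform on
#' \[0.5, 1.5\]) emulates day-to-day litterfall variability; it is off by
#' default for reproducibility.
#'
#' @param deciduous,willow Numeric length-3 rates for the three intervals.
#' @param meadow Numeric length-2 rates for the two intervals.
#' @param upsilon Spruce litter scaling (unitless).
#' @param gpp_coef Coefficients (numerator, offset, exponent rate) of the
#'   GPP response to air temperature.
#' @param litter_coef Coefficients (scale, exponent rate) of the spruce
#'   litter response to GPP.
#' @param jitter `"off"` or `"uniform_multiplicative"`.
#' @return A list of class `"litter_params"`.
#' @export
litter_params <- function(deciduous = c(6e-4, 3e-6, 1.2e-3),
                          meadow = c(3e-8, 3e-7),
                          willow = c(3e-4, 3e-6, 1.2e-3),
                          upsilon = 0.3,
                          gpp_coef = c(1.51, 0.2375, 0.21),
                          litter_coef = c(0.0057, -0.293),
                          jitter = c("off", "uniform_multiplicative")) {
  jitter <- match.arg(jitter)
  if (any(c(deciduous, meadow, willow) < 0) || upsilon < 0) {
    abort("litter rates must be >= 0")
  }
  stopifnot(
    length(deciduous) == 3, length(willow) == 3, length(meadow) == 2
  )
  structure(
    list(
      deciduous = deciduous, meadow = meadow, willow = willow,
      upsilon = upsilon, gpp_coef = gpp_coef, litter_coef = litter_coef,
      jitter = jitter
    ),
    class = "litter_params"
  )
}

#' Cattle excretion parameters
#'
#' DON delivered to soil water by a grazing herd:
#' `F = n_cows * G_i * (L_dung + L_urine)`, where `G_i` is the fraction of
#' the herd present in sub-watershed `i` on a given date. The default
#' schedule follows the local grazing rotation: the full herd in `LT` from
#' July 15 to September 8, then 60% in `ME`, 20% in `Copper` and 10% each
#' in `EAQ` and `Rustlers` from September 9 to October 15.
#'
#' @param n_cows Herd size (default 500).
#' @param L_dung,L_urine Per-head daily DON loads (mol cow^-1 day^-1);
#'   ammonia volatilization is already netted out of these loads.
#' @param schedule Tibble with columns `start_doy`, `end_doy`, `id`,
#'   `G` (herd fraction); intervals may not overlap for one id.
#' @return A list of class `"cattle_params"`.
#' @export
cattle_params <- function(n_cows = 500,
                          L_dung = 8.6,
                          L_urine = 15,
                          schedule = default_grazing_schedule()) {
  if (n_cows < 0 || L_dung < 0 || L_urine < 0) {
    abort("cattle loads must be >= 0")
  }
  stopifnot(all(c("start_doy", "end_doy", "id", "G") %in% names(schedule)))
  if (any(schedule$G < 0)) abort("herd fractions must be >= 0")
  # overlapping intervals for one id are a configuration error
  for (id in unique(schedule$id)) {
    si <- schedule[schedule$id == id, ]
    days <- unlist(Map(seq, si$start_doy, si$end_doy))
    if (anyDuplicated(days)) {
      abort(paste0("overlapping grazing schedule entries for '", id, "'"))
    }
  }
  # total herd fraction must never exceed 1 on any day
  for (d in sort(unique(unlist(Map(seq, schedule$start_doy, schedule$end_doy))))) {
    tot <- sum(schedule$G[schedule$start_doy <= d & schedule$end_doy >= d])
    if (tot > 1 + 1e-9) {
      abort(paste0("herd fractions exceed 1 on day-of-year ", d))
    }
  }
  structure(
    list(
      n_cows = n_cows, L_dung = L_dung, L_urine = L_urine,
      schedule = schedule
    ),
    class = "cattle_params"
  )
}

#' @rdname cattle_params
#' @export
default_grazing_schedule <- function() {
  # Jul 15 = doy 196, Sep 8 = 251, Sep 9 = 252, Oct 15 = 288 (non-leap)
  tibble(
    start_doy = c(196L, 252L, 252L, 252L, 252L),
    end_doy   = c(251L, 288L, 288L, 288L, 288L),
    id        = c("LT", "ME", "Copper", "EAQ", "Rustlers"),
    G         = c(1, 0.6, 0.2, 0.1, 0.1)
  )
}

#' Biological nitrogen fixation parameters
#'
#' Meadow nitrogen fixers (assumed to cover 1% of meadow area) add
#' ammonium at an areal rate drawn uniformly between `lower` and `upper`
#' (mol m^-2 day^-1) whenever soil temperature is above freezing. One draw
#' is made per sub-watershed per day and held constant over that day's
#' hourly steps.
#'
#' @param lower,upper Bounds of the uniform areal rate (mol m^-2 day^-1).
#' @param fixer_fraction Fraction of meadow cover occupied by fixers.
#' @return A list of class `"fixation_params"`.
#' @export
fixation_params <- function(lower = 1e-8,
                            upper = 1e-4,
                            fixer_fraction = 0.01) {
  if (lower < 0 || upper < lower) abort("need 0 <= lower <= upper")
  structure(
    list(lower = lower, upper = upper, fixer_fraction = fixer_fraction),
    class = "fixation_params"
  )
}
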