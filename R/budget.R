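#' Water year of a timestamp
#'
#' Water years run October 1 through September 30 and are labeled by the
#' calendar year in which they end.
#'
#' @param timestamp POSIXct or Date vector.
#' @return Integer water-year labels.
#' @export
water_year <- function(timestamp) {
  yr <- lubridate::year(timestamp)
  ifelse(lubridate::month(timestamp) >= 10, yr + 1L, yr)
}

#' Annual source/sink budget of a simulation
#'
#' Aggregates the flux ledger of one water year into the standard budget
#' categories. Sources: wet deposition (vadose + direct-to-stream, net of
#' any negative wet-deposition terms), dry deposition, shale (Mancos)
#' weathering, biological fixation, litterfall and cattle excretion.
#' Sinks: plant uptake, subsurface denitrification (vadose +
#' groundwater), in-stream loss (in-stream denitrification plus in-stream
#' biological uptake) and downstream export at the terminal outlet.
#'
#' "New" nitrogen is nitrogen entering from outside the plant--soil
#' recycling loop; by default wet + dry deposition, weathering and
#' fixation (litter and cattle re-release previously assimilated
#' nitrogen).
#'
#' @param sim A `watershed_sim` object.
#' @param year Water-year label (see [water_year()]); the ledger must
#'   cover it fully (8760 or 8784 hourly steps).
#' @param new_n_sources Character vector of source categories counted as
#'   new nitrogen.
#' @param partial Set `TRUE` to budget an incomplete water year (the
#'   totals then cover only the steps present).
#' @return A tibble with columns `water_year`, `scenario`, `category`
#'   (`source`/`sink`), `flux`, `mol_yr`, `share_pct`, `new_n` (logical,
#'   sources only) plus attributes `mancos_share_pct` and
#'   `mancos_new_share_pct`.
#' @export
annual_budget <- function(sim, year = NULL,
                          new_n_sources = c(
                            "wet_dep", "dry_dep", "mancos", "fixation"
                          ),
                          partial = FALSE) {
  stopifnot(inherits(sim, "watershed_sim"))
  wy <- water_year(sim$timestamps)
  year <- year %||% wy[1]
  steps <- which(wy == year)
  if (length(steps) == 0) {
    abort(paste0("water year ", year, " is not covered by the run"))
  }
  n_expected <- 24 * (365 + lubridate::leap_year(
    lubridate::make_date(year, 2, 1)
  ))
  if (!partial && length(steps) < n_expected) {
    abort(paste0(
      "water year ", year, " is only partially covered (",
      length(steps), "/", n_expected, " hourly steps); ",
      "pass partial = TRUE to budget it anyway"
    ))
  }

  term <- which(sim$ids == terminal_id(sim))
  outlet <- sum(sim$ledger[steps, term, ledger_cols("stream_export")]) *
    sim$dt_day

  src <- c(
    wet_dep = sum_ledger_kinds(sim, c("wet_dep_vadose", "wet_dep_stream"),
      steps),
    dry_dep = sum_ledger_kinds(sim, "dry_dep", steps),
    mancos = sum_ledger_kinds(sim, c("weathering_vadose", "weathering_gw"),
      steps),
    fixation = sum_ledger_kinds(sim, "fixation", steps),
    litter = sum_ledger_kinds(sim, "litter", steps),
    cattle = sum_ledger_kinds(sim, "cattle", steps)
  )
  snk <- c(
    plant_uptake = sum_ledger_kinds(sim, "uptake_vadose", steps),
    subsurface_denitrification = sum_ledger_kinds(
      sim, c("denitrification_vadose", "denitrification_gw"), steps
    ),
    instream_loss = sum_ledger_kinds(
      sim, c("denitrification_stream", "uptake_stream"), steps
    ),
    downstream_export = outlet
  )

  out <- bind_rows(
    tibble(
      category = "source", flux = names(src), mol_yr = unname(src),
      share_pct = 100 * unname(src) / sum(src),
      new_n = names(src) %in% new_n_sources
    ),
    tibble(
      category = "sink", flux = names(snk), mol_yr = unname(snk),
      share_pct = 100 * unname(snk) / sum(snk),
      new_n = NA
    )
  ) %>%
    mutate(
      water_year = year, scenario = sim$scenario$name,
      .before = 1
    )
  new_total <- sum(src[new_n_sources])
  attr(out, "mancos_share_pct") <- 100 * src[["mancos"]] / sum(src)
  attr(out, "mancos_new_share_pct") <-
    if (new_total > 0) 100 * src[["mancos"]] / new_total else NA_real_
  out
}

#' Closed-form annual shale weathering source
#'
#' Because weathering is constant in time, its annual ledger total has
#' the closed form
#' `sum_i (vadose_share * sigma_i * A_i + gw_share * A_i) * (M_a + M_n + M_o) * days`.
#' Useful as an exact cross-check of ledger accounting on any forcing.
#'
#' @param weathering A [weathering_params()] object.
#' @param descriptors Descriptor table.
#' @param days Number of days in the window (365 by default).
#' @return Total weathering source (mol).
#' @export
mancos_annual_source <- function(weathering,
                                 descriptors = east_river_subwatersheds(),
                                 days = 365) {
  gw_area <- if (weathering$groundwater_area_mode == "full_area") {
    descriptors$area_m2
  } else {
    descriptors$mancos_fraction * descriptors$area_m2
  }
  sum(
    (weathering$vadose_share * descriptors$mancos_fraction *
      descriptors$area_m2 + weathering$groundwater_share * gw_area) *
      sum(weathering$M)
  ) * days
}

#' Calibration balance checks
#'
#' The two manual calibration balance rules: (1) annual litter plus
#' cattle DON release must lie within +/-10% of annual plant uptake;
#' (2) total annual sinks must lie within +/-10% of total annual
#' sources. Ratios with a zero denominator are reported as indeterminate
#' (`NA`, not a pass).
#'
#' @param sim A `watershed_sim` object.
#' @param steps Optional integer step window (defaults to the full run).
#' @param band Relative tolerance band (default 0.1).
#' @return A tibble with one row per check: `check`, `ratio`, `pass`.
#' @export
balance_checks <- function(sim, steps = NULL, band = 0.1) {
  steps <- steps %||% seq_along(sim$timestamps)
  uptake <- sum_ledger_kinds(sim, "uptake_vadose", steps)
  recycle <- sum_ledger_kinds(sim, c("litter", "cattle"), steps)
  sources <- sum_ledger_kinds(sim, setdiff(SOURCE_KINDS, "nonneg_correction"),
    steps)
  term <- which(sim$ids == terminal_id(sim))
  outlet <- sum(sim$ledger[steps, term, ledger_cols("stream_export")]) *
    sim$dt_day
  sinks <- sum_ledger_kinds(sim, SINK_KINDS, steps) + outlet
  ratio1 <- if (uptake > 0) recycle / uptake else NA_real_
  ratio2 <- if (sources > 0) sinks / sources else NA_real_
  tibble(
    check = c("litter_plus_cattle_vs_uptake", "sinks_vs_sources"),
    ratio = c(ratio1, ratio2),
    pass = !is.na(c(ratio1, ratio2)) &
      abs(c(ratio1, ratio2) - 1) <= band
  )
}

#' Root mean square error against observed concentrations
#'
#' Matches each observation to the nearest model timestamp within a
#' tolerance and returns `sqrt(mean((obs - mod)^2))` in uM. Matching is
#' by instantaneous model value (no daily averaging); the result is
#' invariant to observation row order.
#'
#' @param observed Tibble with columns `timestamp`, `subwatershed`,
#'   `species` (`no3`/`nh4`/`don`), `concentration_uM`.
#' @param modeled A `watershed_sim` object or a tidy concentrations
#'   tibble from [tidy.watershed_sim()].
#' @param species,subwatershed Which record to score.
#' @param compartment Model compartment scored (default `"stream"`).
#' @param tolerance_hours Maximum observation--model time offset.
#' @return RMSE in uM (length-1 numeric).
#' @export
rmse_concentration <- function(observed, modeled, species, subwatershed,
                               compartment = "stream",
                               tolerance_hours = 1) {
  if (inherits(modeled, "watershed_sim")) modeled <- tidy(modeled)
  mod <- modeled %>%
    filter(
      .data$species == .env$species,
      .data$subwatershed == .env$subwatershed,
      .data$compartment == .env$compartment
    )
  obs <- observed %>%
    filter(
      .data$species == .env$species,
      .data$subwatershed == .env$subwatershed
    )
  if (nrow(obs) == 0) abort("no observations for that species/subwatershed")
  if (any(obs$concentration_uM < 0)) {
    abort("observed concentrations must be >= 0")
  }
  mt <- as.numeric(mod$timestamp)
  idx <- findInterval(as.numeric(obs$timestamp), mt, all.inside = TRUE)
  # nearest of the two bracketing model steps
  lo <- pmax(idx, 1)
  hi <- pmin(idx + 1, length(mt))
  use_hi <- abs(mt[hi] - as.numeric(obs$timestamp)) <
    abs(mt[lo] - as.numeric(obs$timestamp))
  near <- ifelse(use_hi, hi, lo)
  offset <- abs(mt[near] - as.numeric(obs$timestamp)) / 3600
  ok <- offset <= tolerance_hours
  if (!any(ok)) abort("no observations match a model timestamp in tolerance")
  sqrt(mean((obs$concentration_uM[ok] - mod$uM[near][ok])^2))
}

#' Compare scenario runs on identical forcing
#'
#' Side-by-side budget shares and peak stream concentrations for two or
#' more simulations that share one forcing (verified by hashing the
#' hydrologic inputs); differences relative to the first run are
#' annotated.
#'
#' @param sims A named list of `watershed_sim` objects.
#' @param year Water year to budget (defaults to the first covered).
#' @param partial Passed to [annual_budget()].
#' @return A tibble with one row per (scenario, sub-watershed):
#'   peak stream nitrate/ammonium/DON (uM) plus scenario-level budget
#'   shares, with `delta_*` columns relative to the first run.
#' @export
compare_scenarios <- function(sims, year = NULL, partial = TRUE) {
  stopifnot(length(sims) >= 2)
  hashes <- vapply(sims, function(s) {
    digest_hydro(s$hydro)
  }, character(1))
  if (length(unique(hashes)) != 1) {
    abort("scenario runs must share identical forcing")
  }
  rows <- purrr::imap(sims, function(s, nm) {
    bud <- annual_budget(s, year = year, partial = partial)
    conc <- tidy(s) %>%
      filter(.data$compartment == "stream") %>%
      group_by(.data$subwatershed, .data$species) %>%
      summarise(peak_uM = max(.data$uM), .groups = "drop") %>%
      tidyr::pivot_wider(
        names_from = "species", values_from = "peak_uM",
        names_prefix = "peak_"
      )
    conc %>%
      mutate(
        run = nm,
        scenario = s$scenario$name,
        mancos_share_pct = attr(bud, "mancos_share_pct"),
        instream_loss_share_pct = bud$share_pct[
          bud$category == "sink" & bud$flux == "instream_loss"
        ],
        .before = 1
      )
  })
  out <- bind_rows(rows)
  ref <- out[out$run == names(sims)[1], ]
  out %>%
    left_join(
      ref %>%
        select(
          "subwatershed",
          ref_no3 = "peak_no3", ref_nh4 = "peak_nh4", ref_don = "peak_don"
        ),
      by = "subwatershed"
    ) %>%
    mutate(
      delta_peak_no3 = .data$peak_no3 - .data$ref_no3,
      delta_peak_nh4 = .data$peak_nh4 - .data$ref_nh4,
      delta_peak_don = .data$peak_don - .data$ref_don
    ) %>%
    select(-"ref_no3", -"ref_nh4", -"ref_don")
}

digest_hydro <- function(hydro) {
  key <- hydro %>%
    select("timestamp", "subwatershed", "V_s_m3", "Q_s_m3_day",
      "Q_r_m3_day")
  paste(
    nrow(key),
    format(sum(key$V_s_m3), digits = 15),
    format(sum(key$Q_s_m3_day), digits = 15),
    format(sum(key$Q_r_m3_day), digits = 15),
    sep = "|"
  )
}
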