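FORCING_COLUMNS <- c(
  "timestamp", "subwatershed", "V_s_m3", "V_g_m3", "V_r_m3",
  "infilt_minus_ets_m3_per_hr", "qq_minus_etr_m3_per_hr",
  "T_soil_C", "T_air_C"
)

# Run a block with a private, seed-determined RNG stream, restoring the
# caller's RNG state afterwards.
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic hourly forcing generator
#'
#' The generator emulates the hydrologic regime of a snowmelt-dominated
#' mountain catchment: near-zero infiltration under the winter snowpack, a
#' March--June snowmelt pulse carrying most of the annual water input,
#' evapotranspiration-dominated (negative) net infiltration in summer,
#' late-summer monsoon rain events, and seasonal air/soil temperature
#' cycles. Water is routed through linear vadose, groundwater and stream
#' reservoirs so that the emitted storage volumes are mutually consistent
#' with the emitted net-infiltration and overland-flow series.
#'
#' All water-input parameters are areal rates (m day^-1) scaled by each
#' sub-watershed's area, so the same configuration serves catchments of
#' different size.
#'
#' @param seed Integer; fully determines the generated series.
#' @param n_years Number of calendar years to generate (default 1).
#' @param origin Start of the series (water-year start), default
#'   `"2014-10-01"` UTC.
#' @param melt_amp_m_day Peak areal snowmelt infiltration (m day^-1).
#' @param melt_peak_doy,melt_sd_days Center and width (days) of the
#'   Gaussian melt pulse.
#' @param winter_infilt_m_day Background winter infiltration (m day^-1).
#' @param summer_et_m_day Magnitude of net summer soil-water loss
#'   (m day^-1, applied as negative infiltration July--October).
#' @param monsoon_events Expected number of monsoon rain events per year.
#' @param monsoon_amp_m_day Mean areal event intensity (m day^-1).
#' @param vs_base_m,vg_base_m Baseline vadose/groundwater storage expressed
#'   as water depth over the sub-watershed (m).
#' @param k_s_day,k_g_day,k_r_day First-order outflow rates of the vadose,
#'   groundwater and stream reservoirs (day^-1); their inverses set the
#'   characteristic residence times.
#' @param t_air_mean_C,t_air_amp_C,t_soil_mean_C,t_soil_amp_C Annual mean
#'   and amplitude of the air and soil temperature sinusoids (degrees C).
#'   Soil temperature is clamped to \[-5, 20\] degrees C.
#' @param noise_sd Relative white-noise level on the melt pulse.
#' @return A list of class `"forcing_config"`.
#' @export
forcing_config <- function(seed = 1L,
                           n_years = 1,
                           origin = "2014-10-01",
                           melt_amp_m_day = 0.007,
                           melt_peak_doy = 125,
                           melt_sd_days = 28,
                           winter_infilt_m_day = 2e-4,
                           summer_et_m_day = 1.2e-3,
                           monsoon_events = 8,
                           monsoon_amp_m_day = 6e-3,
                           vs_base_m = 0.18,
                           vg_base_m = 1.1,
                           k_s_day = 0.025,
                           k_g_day = 0.01,
                           k_r_day = 0.5,
                           t_air_mean_C = 2,
                           t_air_amp_C = 12,
                           t_soil_mean_C = 3.5,
                           t_soil_amp_C = 5.5,
                           noise_sd = 0.1) {
  cfg <- as.list(environment())
  if (cfg$n_years <= 0) abort("n_years must be positive")
  if (cfg$melt_amp_m_day < 0 || cfg$monsoon_amp_m_day < 0) {
    abort("pulse amplitudes must be non-negative")
  }
  structure(cfg, class = "forcing_config")
}

#' Generate synthetic hourly forcing for a routed watershed
#'
#' Produces an hourly forcing table with the columns required by
#' [read_forcing()]: storage volumes of the vadose, groundwater and stream
#' compartments, net infiltration minus soil evapotranspiration, overland
#' flow minus stream evapotranspiration, and soil/air temperatures, for
#' every sub-watershed on one shared time axis. Identical seeds give
#' byte-identical output; the caller's RNG state is left untouched.
#'
#' @param config A [forcing_config()].
#' @param descriptors Sub-watershed table, see [east_river_subwatersheds()].
#' @param baseflow Baseflow schedule used for internal routing, see
#'   [default_baseflow_schedule()].
#' @return A forcing tibble (one row per timestamp and sub-watershed).
#' @examples
#' f <- generate_forcing(forcing_config(seed = 42, n_years = 1))
#' dplyr::count(f, subwatershed)
#' @export
generate_forcing <- function(config = forcing_config(),
                             descriptors = east_river_subwatersheds(),
                             baseflow = default_baseflow_schedule(descriptors)) {
  stopifnot(inherits(config, "forcing_config"))
  validate_descriptors(descriptors)
  with_private_seed(config$seed, {
    origin <- lubridate::as_datetime(config$origin, tz = "UTC")
    end <- lubridate::add_with_rollback(origin, lubridate::years(config$n_years))
    ts <- seq(origin, end - lubridate::dhours(1), by = "hour")
    n <- length(ts)
    doy <- lubridate::yday(ts)
    hr <- lubridate::hour(ts)
    dt_day <- 1 / 24

    # shared temperature fields (watershed-wide seasonal cycles)
    t_air <- config$t_air_mean_C +
      config$t_air_amp_C * cos(2 * pi * (doy - 205) / 365.25) +
      3 * sin(2 * pi * (hr - 9) / 24) +
      stats::rnorm(n, sd = 1.2)
    t_soil_base <- config$t_soil_mean_C +
      config$t_soil_amp_C * cos(2 * pi * (doy - 222) / 365.25)

    # monsoon events: shared storm timing across the watershed, drawn once
    years <- unique(lubridate::year(ts))
    monsoon_rate <- numeric(n) # areal m/day
    for (yy in years) {
      in_window <- lubridate::year(ts) == yy & doy >= 213 & doy <= 304
      if (!any(in_window)) next
      n_ev <- stats::rpois(1, config$monsoon_events)
      if (n_ev == 0) next
      idx_window <- which(in_window)
      starts <- sort(sample(idx_window, n_ev, replace = TRUE))
      for (s in starts) {
        len <- sample(8:30, 1) # storm duration, hours
        mag <- config$monsoon_amp_m_day * runif(1, 0.5, 1.5)
        iend <- min(s + len - 1, n)
        monsoon_rate[s:iend] <- monsoon_rate[s:iend] + mag
      }
    }

    melt_shape <- exp(-0.5 * ((doy - config$melt_peak_doy) /
      config$melt_sd_days)^2)
    melt_rate <- config$melt_amp_m_day * melt_shape *
      pmax(0, 1 + config$noise_sd * stats::rnorm(n))
    summer <- doy >= 182 & doy <= 304
    et_rate <- ifelse(summer, config$summer_et_m_day, 0) *
      (0.7 + 0.3 * runif(n))
    infilt_rate <- config$winter_infilt_m_day + melt_rate +
      monsoon_rate - et_rate # areal m/day, signed

    out <- vector("list", nrow(descriptors))
    q_r_store <- list() # outlet flow per sub-watershed, m^3/day
    order_ids <- topological_order(descriptors)
    for (id in order_ids) {
      d <- descriptors[descriptors$id == id, ]
      A <- d$area_m2
      beta <- beta_at(baseflow, id, doy)

      infilt <- infilt_rate * A # m^3/day (signed)
      qq <- (0.08 * (melt_rate + monsoon_rate) -
        ifelse(summer, 5e-5, 0)) * A # m^3/day

      # vadose reservoir: dV/dt = infilt - k_s (V - Vmin)
      vs_min <- 0.6 * config$vs_base_m * A
      vs0 <- config$vs_base_m * A
      a_s <- 1 - config$k_s_day * dt_day
      b_s <- (infilt + config$k_s_day * vs_min) * dt_day
      v_s <- c(vs0, stats::filter(b_s, a_s, "recursive", init = vs0))[1:n]
      q_s <- config$k_s_day * (v_s - vs_min) # m^3/day, signed

      # groundwater reservoir: recharge beta*q_s (q_s>0) else q_s
      recharge <- ifelse(q_s > 0, beta * q_s, q_s)
      vg_min <- 0.8 * config$vg_base_m * A
      vg0 <- config$vg_base_m * A
      a_g <- 1 - config$k_g_day * dt_day
      b_g <- (recharge + config$k_g_day * vg_min) * dt_day
      v_g <- c(vg0, stats::filter(b_g, a_g, "recursive", init = vg0))[1:n]
      q_g <- config$k_g_day * (v_g - vg_min)

      upstream <- Reduce(`+`, q_r_store[
        descriptors$id[!is.na(descriptors$downstream_id) &
          descriptors$downstream_id == id]
      ], accumulate = FALSE) %||% 0

      inflow <- (1 - beta) * pmax(q_s, 0) + q_g + qq + upstream
      vr0 <- max(mean(pmax(inflow, 0)), 1) / config$k_r_day
      a_r <- 1 - config$k_r_day * dt_day
      b_r <- inflow * dt_day
      v_r <- c(vr0, stats::filter(b_r, a_r, "recursive", init = vr0))[1:n]
      q_r_store[[id]] <- config$k_r_day * v_r

      t_soil <- pmin(20, pmax(-5, t_soil_base +
        stats::rnorm(n, sd = 0.15)))

      if (min(v_s) <= 0 || min(v_g) <= 0 || min(v_r) <= 0) {
        abort(paste0(
          "forcing_config parameters produce non-positive storage in '",
          id, "'; increase baseline storages or reduce losses"
        ))
      }

      out[[id]] <- tibble(
        timestamp = ts,
        subwatershed = id,
        V_s_m3 = v_s,
        V_g_m3 = v_g,
        V_r_m3 = v_r,
        infilt_minus_ets_m3_per_hr = infilt / 24,
        qq_minus_etr_m3_per_hr = qq / 24,
        T_soil_C = t_soil,
        T_air_C = t_air
      )
    }
    bind_rows(out[descriptors$id]) %>%
      arrange(.data$timestamp, .data$subwatershed)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate an hourly forcing table
#'
#' Checks column presence, strictly positive storages, a complete and
#' uniform hourly time axis shared by every sub-watershed, and sorts rows
#' into the canonical (timestamp, sub-watershed) order.
#'
#' @param forcing A forcing tibble (see [generate_forcing()] for columns).
#' @param descriptors Descriptor table the forcing must cover.
#' @return The validated, sorted tibble.
#' @export
validate_forcing <- function(forcing,
                             descriptors = east_river_subwatersheds()) {
  missing_cols <- setdiff(FORCING_COLUMNS, names(forcing))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "forcing table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  forcing <- forcing %>%
    arrange(.data$timestamp, .data$subwatershed)
  missing_sw <- setdiff(descriptors$id, unique(forcing$subwatershed))
  if (length(missing_sw) > 0) {
    abort(paste0(
      "forcing lacks sub-watershed(s): ", paste(missing_sw, collapse = ", ")
    ))
  }
  for (col in c("V_s_m3", "V_g_m3", "V_r_m3")) {
    bad <- which(forcing[[col]] <= 0)
    if (length(bad) > 0) {
      abort(paste0(
        "non-positive ", col, " at timestamp ",
        format(forcing$timestamp[bad[1]], tz = "UTC"),
        " (", forcing$subwatershed[bad[1]], ")"
      ))
    }
  }
  axes <- forcing %>%
    group_by(.data$subwatershed) %>%
    summarise(
      n = dplyr::n(),
      uniform = all(abs(diff(as.numeric(.data$timestamp)) - 3600) < 1e-6),
      first = min(.data$timestamp),
      .groups = "drop"
    )
  if (length(unique(axes$n)) != 1 || length(unique(axes$first)) != 1) {
    abort("all sub-watersheds must share one time axis")
  }
  if (!all(axes$uniform)) {
    bad <- axes$subwatershed[!axes$uniform][1]
    abort(paste0(
      "time axis is not uniformly hourly for sub-watershed '", bad, "'"
    ))
  }
  forcing
}

#' Read an hourly forcing table from CSV
#'
#' Expects the canonical dialect written by [write_forcing()]: ISO-8601
#' timestamps and one row per (timestamp, sub-watershed).
#'
#' @param path Path to a CSV file.
#' @inheritParams validate_forcing
#' @return A validated forcing tibble.
#' @export
read_forcing <- function(path, descriptors = east_river_subwatersheds()) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      subwatershed = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_forcing(raw, descriptors)
}

#' Write an hourly forcing table to CSV (canonical dialect)
#'
#' The canonical dialect uses ISO-8601 UTC timestamps and fixed
#' six-decimal numeric formatting, so that a load/write cycle of a
#' canonical file is byte-identical.
#'
#' @param forcing A forcing tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forcing <- function(forcing, path) {
  out <- forcing %>%
    arrange(.data$timestamp, .data$subwatershed) %>%
    mutate(
      timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ",
        tz = "UTC"),
      across(!c("timestamp", "subwatershed"), ~ sprintf("%.6f", .x))
    )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
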