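SCENARIO_NAMES <- c("C1", "C2", "C3", "NM1", "NM2", "NC")

#' Load a packaged calibration scenario
#'
#' Six manually calibrated parameter sets spanning different regions of
#' the parameter space that fit the observed stream nitrate record about
#' equally well (an equifinality ensemble):
#'
#' * `C1` -- prevalent subsurface cycling: low in-stream reactivity, high
#'   vadose reactivity, moderate shale weathering, moderate groundwater
#'   denitrification.
#' * `C2` -- prevalent surface-water cycling (the most plausible set):
#'   high in-stream reactivity, low vadose reactivity, moderate shale
#'   weathering, low groundwater denitrification.
#' * `C3` -- both surface and subsurface cycling, with the largest shale
#'   weathering flux for which a calibration could be achieved.
#' * `NM1`, `NM2` -- no-shale counterparts of `C1` and `C2`
#'   (all weathering fluxes zero).
#' * `NC` -- the `C2`-like watershed without cattle (`n_cows = 0`,
#'   litter scaled up to compensate).
#'
#' Every component of the returned set can be overridden by replacing the
#' corresponding element before passing it to [simulate_watershed()].
#'
#' @param name One of `"C1"`, `"C2"`, `"C3"`, `"NM1"`, `"NM2"`, `"NC"`.
#' @return A list of class `"scenario_params"` with elements
#'   `name`, `vadose_rates`, `stream_rates`, `gw_denit`, `weathering`,
#'   `litter`, `cattle`, `deposition`, `uptake`, `fixation`.
#' @examples
#' load_scenario("C2")$vadose_rates
#' @export
load_scenario <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
    !(name %in% SCENARIO_NAMES)) {
    abort(paste0(
      "unknown scenario '", paste(name, collapse = ","),
      "'; valid names: ", paste(SCENARIO_NAMES, collapse = ", ")
    ))
  }
  vr <- switch(name,
    C1 = vadose_rate_table(
      k_nit = c(df = 2.5, cf = 2.5, ms = 2.5, ww = 2.5),
      k_min = c(df = 2.4, cf = 2.4, ms = 1.8, ww = 2.4),
      k_den = c(df = 1.2, cf = 1.2, ms = 1.2, ww = 6)
    ),
    C2 = vadose_rate_table(
      k_nit = c(df = 0.05, cf = 0.05, ms = 0.05, ww = 0.09),
      k_min = c(df = 0.2, cf = 0.2, ms = 0.15, ww = 0.7),
      k_den = c(df = 0.001, cf = 0.001, ms = 0.001, ww = 0.001)
    ),
    C3 = vadose_rate_table(
      k_nit = c(df = 2.5, cf = 2.5, ms = 2.5, ww = 2.5),
      k_min = c(df = 2.4, cf = 2.4, ms = 1.8, ww = 2.4),
      k_den = c(df = 7.5, cf = 7.5, ms = 7.5, ww = 7.5)
    ),
    NM1 = vadose_rate_table(
      k_nit = c(df = 2.5, cf = 2.5, ms = 2.5, ww = 2.5),
      k_min = c(df = 2.4, cf = 2.4, ms = 1.8, ww = 2.4),
      k_den = c(df = 0.2, cf = 0.2, ms = 0.2, ww = 1)
    ),
    NM2 = vadose_rate_table(
      k_nit = c(df = 0.05, cf = 0.05, ms = 0.05, ww = 0.09),
      k_min = c(df = 0.2, cf = 0.2, ms = 0.15, ww = 0.7),
      k_den = c(df = 5e-4, cf = 5e-4, ms = 5e-4, ww = 5e-4)
    ),
    NC = vadose_rate_table(
      k_nit = c(df = 0.05, cf = 0.05, ms = 0.05, ww = 0.09),
      k_min = c(df = 0.2, cf = 0.2, ms = 0.15, ww = 0.7),
      k_den = c(df = 0.001, cf = 0.001, ms = 0.001, ww = 0.001)
    )
  )
  sr <- switch(name,
    C1 = stream_rate_params(k20_nit = 0.3, k20_up = 1.0, k20_den = 0.4),
    C2 = stream_rate_params(k20_nit = 5.0, k20_up = 2.0, k20_den = 1.0),
    C3 = stream_rate_params(k20_nit = 5.0, k20_up = 1.0, k20_den = 1.0),
    NM1 = stream_rate_params(k20_nit = 0.3, k20_up = 1.0, k20_den = 0.4),
    NM2 = stream_rate_params(k20_nit = 5.0, k20_up = 2.0, k20_den = 0.5),
    NC = stream_rate_params(k20_nit = 5.0, k20_up = 2.0, k20_den = 1.0)
  )
  gw <- gw_denit_params(k_den_max = switch(name,
    C1 = 0.02, C2 = 0.001, C3 = 2.5, NM1 = 0.001, NM2 = 5e-4, NC = 0.001
  ))
  we <- switch(name,
    C1 = ,
    C2 = ,
    NC = weathering_params(M_a = 2.0e-7, M_n = 7.5e-6, M_o = 7.5e-6),
    C3 = weathering_params(M_a = 6.0e-7, M_n = 2.25e-5, M_o = 2.25e-5),
    NM1 = ,
    NM2 = weathering_params(M_a = 0, M_n = 0, M_o = 0)
  )
  li <- switch(name,
    C1 = litter_params(
      deciduous = c(0.001, 5e-6, 0.002), meadow = c(5e-8, 5e-7),
      willow = c(5e-4, 5e-6, 0.002), upsilon = 0.5
    ),
    C2 = litter_params(
      deciduous = c(6e-4, 3e-6, 0.0012), meadow = c(3e-8, 3e-7),
      willow = c(3e-4, 3e-6, 0.0012), upsilon = 0.3
    ),
    C3 = litter_params(
      deciduous = c(2e-4, 1e-6, 4e-4), meadow = c(1e-8, 1e-7),
      willow = c(1e-4, 1e-6, 4e-4), upsilon = 0.1
    ),
    NM1 = litter_params(
      deciduous = c(0.001, 5e-6, 0.002), meadow = c(5e-8, 5e-7),
      willow = c(5e-4, 5e-6, 0.002), upsilon = 0.5
    ),
    NM2 = litter_params(
      deciduous = c(7e-4, 3e-6, 0.007), meadow = c(3e-8, 3e-7),
      willow = c(3e-4, 3e-6, 0.00125), upsilon = 0.3
    ),
    NC = litter_params(
      deciduous = c(0.0014, 7e-6, 0.0028), meadow = c(7e-8, 7e-7),
      willow = c(7e-4, 7e-6, 0.0028), upsilon = 0.7
    )
  )
  ca <- if (name == "NC") cattle_params(n_cows = 0) else cattle_params()
  structure(
    list(
      name = name,
      vadose_rates = vr,
      stream_rates = sr,
      gw_denit = gw,
      weathering = we,
      litter = li,
      cattle = ca,
      deposition = deposition_params(),
      uptake = uptake_params(),
      fixation = fixation_params()
    ),
    class = "scenario_params"
  )
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("<scenario_params>", x$name, "\n")
  cat("  weathering M (a/n/o, mol m^-2 day^-1): ",
    paste(signif(x$weathering$M, 3), collapse = " / "), "\n",
    sep = ""
  )
  cat("  stream k20 (nit/up/den/min, day^-1):   ",
    paste(signif(x$stream_rates$k20, 3), collapse = " / "), "\n",
    sep = ""
  )
  cat("  gw k_den_max (day^-1): ", x$gw_denit$k_den_max,
    "   cows: ", x$cattle$n_cows, "\n",
    sep = ""
  )
  invisible(x)
}

#' A zero-reaction, zero-source "tracer" parameter set
#'
#' All biological rate constants, sources and exchanges with the
#' atmosphere/bedrock are zero; nitrogen only moves with water. Useful for
#' conservation testing: total stored nitrogen plus cumulative outlet
#' export must remain constant.
#'
#' @return A `"scenario_params"` list.
#' @export
tracer_scenario <- function() {
  s <- load_scenario("C2")
  s$name <- "tracer"
  s$vadose_rates <- vadose_rate_table(
    k_nit = c(df = 0, cf = 0, ms = 0, ww = 0),
    k_min = c(df = 0, cf = 0, ms = 0, ww = 0),
    k_den = c(df = 0, cf = 0, ms = 0, ww = 0)
  )
  s$stream_rates <- stream_rate_params(
    k20_nit = 0, k20_up = 0, k20_den = 0, k20_min = 0
  )
  s$gw_denit <- gw_denit_params(k_den_max = 0)
  s$weathering <- weathering_params(M_a = 0, M_n = 0, M_o = 0)
  s$litter <- litter_params(
    deciduous = c(0, 0, 0), meadow = c(0, 0), willow = c(0, 0, 0),
    upsilon = 0
  )
  s$cattle <- cattle_params(n_cows = 0)
  s$deposition <- deposition_params(
    wet_no3 = 0, wet_nh4 = 0, wet_don = 0,
    dry_no3 = 0, dry_nh4 = 0, dry_don = 0
  )
  s$uptake$f_max[] <- 0
  s$fixation <- fixation_params(lower = 0, upper = 0)
  s
}
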