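#' Sub-watershed descriptors for the modeled catchment
#'
#' Static geometry, land-cover fractions, shale (Mancos) coverage and
#' routing for the five modeled sub-watersheds of the East River headwaters:
#' the East River above Quigley Creek (`EAQ`), Rustlers Gulch, Copper Creek,
#' the Middle East River (`ME`) and the lower triangle (`LT`) draining to
#' the pumphouse outlet. The three headwater catchments route to `ME`,
#' which routes to `LT`; `LT` is the terminal node (`downstream_id = NA`).
#'
#' Land-cover fractions need not sum to 1: the remainder is barren or
#' developed area with all biological rate constants equal to zero.
#'
#' @return A tibble with one row per sub-watershed and columns
#'   `id`, `area_m2`, `frac_deciduous`, `frac_coniferous`, `frac_meadow`,
#'   `frac_willow`, `mancos_fraction`, `downstream_id`.
#' @examples
#' east_river_subwatersheds()
#' @export
east_river_subwatersheds <- function() {
  tibble(
    id              = c("EAQ", "Rustlers", "Copper", "ME", "LT"),
    area_m2         = c(5.27e6, 1.48e7, 2.37e7, 2.61e7, 1.49e7),
    frac_deciduous  = c(0.131, 0.013, 0.023, 0.125, 0.330),
    frac_coniferous = c(0.205, 0.189, 0.194, 0.353, 0.135),
    frac_meadow     = c(0.310, 0.468, 0.278, 0.274, 0.422),
    frac_willow     = c(0.122, 0.118, 0.049, 0.058, 0.075),
    mancos_fraction = c(0.70, 0.08, 0.01, 0.18, 0.18),
    downstream_id   = c("ME", "ME", "ME", "LT", NA_character_)
  )
}

#' Validate a sub-watershed descriptor table
#'
#' Checks the structural invariants a descriptor table must satisfy before
#' it can drive the hydrologic or nitrogen model: positive areas, cover and
#' shale fractions in \[0, 1\] with total vegetated cover at most 1, and an
#' acyclic routing graph with exactly one terminal (outlet) node.
#'
#' @param descriptors A tibble shaped like [east_river_subwatersheds()].
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_descriptors <- function(descriptors) {
  required <- c(
    "id", "area_m2", "frac_deciduous", "frac_coniferous",
    "frac_meadow", "frac_willow", "mancos_fraction", "downstream_id"
  )
  missing_cols <- setdiff(required, names(descriptors))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "descriptor table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(descriptors$id)) {
    abort("descriptor ids must be unique")
  }
  if (any(descriptors$area_m2 <= 0)) {
    abort("all sub-watershed areas must be positive")
  }
  fr <- descriptors[, c(
    "frac_deciduous", "frac_coniferous", "frac_meadow", "frac_willow"
  )]
  if (any(as.matrix(fr) < 0) || any(as.matrix(fr) > 1)) {
    abort("land-cover fractions must lie in [0, 1]")
  }
  if (any(rowSums(as.matrix(fr)) > 1 + 1e-9)) {
    abort("land-cover fractions must sum to at most 1 per sub-watershed")
  }
  if (any(descriptors$mancos_fraction < 0 | descriptors$mancos_fraction > 1)) {
    abort("mancos_fraction must lie in [0, 1]")
  }
  bad_ds <- setdiff(
    descriptors$downstream_id[!is.na(descriptors$downstream_id)],
    descriptors$id
  )
  if (length(bad_ds) > 0) {
    abort(paste0("unknown downstream id(s): ", paste(bad_ds, collapse = ", ")))
  }
  n_terminal <- sum(is.na(descriptors$downstream_id))
  if (n_terminal != 1) {
    abort("routing graph must have exactly one terminal (outlet) node")
  }
  # acyclicity: walking downstream from any node must reach the outlet
  ds <- setNames(descriptors$downstream_id, descriptors$id)
  for (start in descriptors$id) {
    seen <- character(0)
    node <- start
    while (!is.na(node)) {
      if (node %in% seen) abort("routing graph contains a cycle")
      seen <- c(seen, node)
      node <- ds[[node]]
    }
  }
  invisible(descriptors)
}

#' Topological ordering of sub-watersheds
#'
#' Orders sub-watersheds headwaters-first so that every upstream outlet is
#' resolved before the reach receiving it.
#'
#' @inheritParams validate_descriptors
#' @return Character vector of ids in upstream-to-downstream order.
#' @export
topological_order <- function(descriptors) {
  validate_descriptors(descriptors)
  ds <- setNames(descriptors$downstream_id, descriptors$id)
  depth <- vapply(descriptors$id, function(start) {
    d <- 0L
    node <- ds[[start]]
    while (!is.na(node)) {
      d <- d + 1L
      node <- ds[[node]]
    }
    d
  }, integer(1))
  descriptors$id[order(-depth, descriptors$id)]
}

#' Seasonal baseflow-index schedule
#'
#' The baseflow index `beta` is the fraction of positive vadose-zone
#' outflow routed to groundwater (the remaining `1 - beta` share is
#' interflow delivered directly to the stream). It varies by hydrologic
#' season: winter baseflow, rising limb (snowmelt onset), falling limb,
#' and the late-summer monsoon.
#'
#' The shipped default values are placeholders in the plausible range for
#' snowmelt-dominated catchments (the calibrated per-catchment values in
#' the source hydrology are not published): winter 0.9, rising 0.5,
#' falling 0.6, monsoon 0.7, identical across sub-watersheds, with
#' day-of-year windows winter 305--59, rising 60--151, falling 152--212,
#' monsoon 213--304. Both the values and the windows are configurable by
#' editing the returned tibble.
#'
#' @param descriptors Descriptor table; one schedule row set per id.
#' @param beta Named numeric vector of the four seasonal values.
#' @return A tibble with columns `id`, `season`, `doy_start`, `doy_end`,
#'   `beta`. Winter wraps across the new year (`doy_start > doy_end`).
#' @export
default_baseflow_schedule <- function(descriptors = east_river_subwatersheds(),
                                      beta = c(
                                        winter = 0.9, rising = 0.5,
                                        falling = 0.6, monsoon = 0.7
                                      )) {
  seasons <- tibble(
    season    = c("winter", "rising", "falling", "monsoon"),
    doy_start = c(305L, 60L, 152L, 213L),
    doy_end   = c(59L, 151L, 212L, 304L),
    beta      = unname(beta[c("winter", "rising", "falling", "monsoon")])
  )
  tidyr::crossing(id = descriptors$id, seasons) %>%
    arrange(.data$id)
}

#' Resolve the baseflow index for given days of year
#'
#' @param schedule A schedule tibble from [default_baseflow_schedule()].
#' @param id Single sub-watershed id.
#' @param doy Integer vector of days of year (1--366).
#' @return Numeric vector of beta values, one per element of `doy`.
#' @export
beta_at <- function(schedule, id, doy) {
  sched <- schedule[schedule$id == id, ]
  if (nrow(sched) == 0) {
    abort(paste0("no baseflow schedule for sub-watershed '", id, "'"))
  }
  out <- rep(NA_real_, length(doy))
  for (k in seq_len(nrow(sched))) {
    s <- sched$doy_start[k]
    e <- sched$doy_end[k]
    hit <- if (s <= e) doy >= s & doy <= e else doy >= s | doy <= e
    out[hit] <- sched$beta[k]
  }
  if (anyNA(out)) {
    abort("baseflow schedule does not cover every day of year")
  }
  out
}
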