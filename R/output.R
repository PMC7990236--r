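#' Tidy a simulation into a long concentrations table
#'
#' One row per (timestamp, sub-watershed, compartment, species) with the
#' pool in mol and its concentration in uM (1 mol m^-3 = 1000 uM),
#' computed against the compartment water volume at that step.
#'
#' @param x A `watershed_sim` object.
#' @param ... Unused.
#' @return A tibble with columns `timestamp`, `subwatershed`,
#'   `compartment` (`vadose`/`stream`/`groundwater`), `species`
#'   (`nh4`/`no3`/`don`), `mol`, `uM`.
#' @method tidy watershed_sim
#' @export
tidy.watershed_sim <- function(x, ...) {
  n_steps <- length(x$timestamps)
  comp_names <- c(s = "vadose", r = "stream", g = "groundwater")
  sp_names <- c(a = "nh4", n = "no3", o = "don")
  vol_col <- c(s = "V_s_m3", r = "V_r_m3", g = "V_g_m3")
  hydro <- x$hydro %>% arrange(.data$timestamp, .data$subwatershed)
  out <- list()
  for (p in seq_along(POOL_NAMES)) {
    sp <- substr(POOL_NAMES[p], 1, 1)
    comp <- substr(POOL_NAMES[p], 3, 3)
    # states are indexed [step, sw]; row-major flattening matches the
    # (timestamp, subwatershed) sorted hydro table
    mol <- as.vector(t(x$states[seq_len(n_steps), , p]))
    vol <- hydro[[vol_col[[comp]]]]
    out[[p]] <- tibble(
      timestamp = hydro$timestamp,
      subwatershed = hydro$subwatershed,
      compartment = comp_names[[comp]],
      species = sp_names[[sp]],
      mol = mol,
      uM = mol / vol * 1000
    )
  }
  bind_rows(out) %>%
    arrange(
      .data$timestamp, .data$subwatershed, .data$compartment,
      .data$species
    )
}

#' One-row summary of a simulation
#'
#' @param x A `watershed_sim` object.
#' @param ... Unused.
#' @return A tibble with the run length, total initial and final stored
#'   nitrogen, cumulative outlet export, total sources and sinks from the
#'   ledger, the ledger-vs-state closure error and limiter statistics.
#' @method glance watershed_sim
#' @export
glance.watershed_sim <- function(x, ...) {
  cl <- ledger_closure(x)
  tibble(
    n_steps = length(x$timestamps),
    n_subwatersheds = length(x$ids),
    scenario = x$scenario$name,
    initial_mol = cl$initial_mol,
    final_mol = cl$final_mol,
    outlet_export_mol = cl$outlet_export_mol,
    sources_mol = cl$sources_mol,
    sinks_mol = cl$sinks_mol,
    closure_rel_error = cl$rel_error,
    limiter_events = x$log$n_limited,
    clamped_pools = x$log$n_nonneg
  )
}

#' Tidy the flux ledger
#'
#' @param sim A `watershed_sim` object.
#' @param drop_zero Drop all-zero flux/species combinations (default
#'   `TRUE`).
#' @return A tibble with columns `timestamp`, `subwatershed`, `flux`,
#'   `species`, `mol_per_day` (stage-weighted mean rate over each step).
#' @export
tidy_ledger <- function(sim, drop_zero = TRUE) {
  stopifnot(inherits(sim, "watershed_sim"))
  led <- sim$ledger
  cols <- dimnames(led)[[3]]
  keep <- if (drop_zero) {
    which(apply(led != 0, 3, any))
  } else {
    seq_along(cols)
  }
  out <- list()
  for (k in keep) {
    parts <- strsplit(cols[k], ".", fixed = TRUE)[[1]]
    out[[length(out) + 1]] <- tibble(
      timestamp = rep(sim$timestamps, times = length(sim$ids)),
      subwatershed = rep(sim$ids, each = length(sim$timestamps)),
      flux = parts[1],
      species = c(a = "nh4", n = "no3", o = "don")[[parts[2]]],
      mol_per_day = as.vector(led[, , k])
    )
  }
  bind_rows(out) %>%
    arrange(.data$timestamp, .data$subwatershed, .data$flux, .data$species)
}

# Source, sink and export ledger kinds used for mass closure and budgets.
SOURCE_KINDS <- c(
  "wet_dep_vadose", "dry_dep", "weathering_vadose", "weathering_gw",
  "fixation", "litter", "cattle", "wet_dep_stream", "nonneg_correction"
)
SINK_KINDS <- c(
  "uptake_vadose", "denitrification_vadose", "uptake_stream",
  "denitrification_stream", "denitrification_gw"
)

# Sum a set of ledger kinds over steps (and optionally sub-watersheds),
# returning mol over the window (rates integrated at dt).
sum_ledger_kinds <- function(sim, kinds, steps = NULL, per_species = FALSE) {
  steps <- steps %||% seq_along(sim$timestamps)
  idx <- unlist(lapply(kinds, ledger_cols))
  led <- sim$ledger[steps, , idx, drop = FALSE]
  tot <- apply(led, 3, sum) * sim$dt_day
  if (!per_species) {
    return(sum(tot))
  }
  sp <- rep(N_SPECIES, times = length(kinds))
  tapply(tot, sp, sum)[N_SPECIES]
}

#' Ledger-vs-state mass closure
#'
#' Verifies whole-system nitrogen conservation: the change in total
#' stored nitrogen over the run must equal ledger sources minus ledger
#' sinks minus outlet export (net stream export at the terminal node).
#'
#' @param sim A `watershed_sim` object.
#' @param steps Optional integer step window.
#' @return A list with the component totals (mol) and the relative
#'   closure error (`rel_error`, scaled by total nitrogen throughput).
#' @export
ledger_closure <- function(sim, steps = NULL) {
  steps <- steps %||% seq_along(sim$timestamps)
  initial <- sum(sim$states[min(steps), , ])
  final <- sum(sim$states[max(steps) + 1, , ])
  sources <- sum_ledger_kinds(sim, SOURCE_KINDS, steps)
  sinks <- sum_ledger_kinds(sim, SINK_KINDS, steps)
  term <- which(sim$ids == terminal_id(sim))
  outlet <- sum(sim$ledger[steps, term, ledger_cols("stream_export")]) *
    sim$dt_day
  delta <- final - initial
  balance <- sources - sinks - outlet
  scale <- max(abs(initial), abs(sources), abs(sinks), abs(outlet), 1)
  list(
    initial_mol = initial, final_mol = final,
    sources_mol = sources, sinks_mol = sinks,
    outlet_export_mol = outlet,
    rel_error = abs(delta - balance) / scale
  )
}

terminal_id <- function(sim) {
  sim$descriptors$id[is.na(sim$descriptors$downstream_id)]
}

#' @export
print.watershed_sim <- function(x, ...) {
  cat(
    "<watershed_sim> scenario", x$scenario$name, "|",
    length(x$timestamps), "hourly steps |",
    length(x$ids), "sub-watersheds\n"
  )
  cat("  ", format(min(x$timestamps), tz = "UTC"), "to",
    format(max(x$timestamps), tz = "UTC"), "\n")
  g <- glance(x)
  cat("   total N:", format(g$initial_mol, digits = 4), "->",
    format(g$final_mol, digits = 4), "mol; outlet export",
    format(g$outlet_export_mol, digits = 4), "mol\n")
  invisible(x)
}

#' Write simulation outputs to disk
#'
#' Writes `concentrations.csv` (long pool/concentration table),
#' `ledger.csv` (long flux ledger) and `manifest.txt` (scenario, seed,
#' run window, package version) into `outdir`.
#'
#' @param sim A `watershed_sim` object.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_outputs <- function(sim, outdir) {
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  conc <- tidy(sim)
  readr::write_csv(conc, file.path(outdir, "concentrations.csv"),
    progress = FALSE)
  readr::write_csv(tidy_ledger(sim), file.path(outdir, "ledger.csv"),
    progress = FALSE)
  manifest <- c(
    paste0("package: riverN ", as.character(utils::packageVersion("riverN"))),
    paste0("scenario: ", sim$scenario$name),
    paste0("seed: ", sim$seed),
    paste0("n_steps: ", length(sim$timestamps)),
    paste0("start: ", format(min(sim$timestamps), tz = "UTC")),
    paste0("end: ", format(max(sim$timestamps), tz = "UTC")),
    paste0("subwatersheds: ", paste(sim$ids, collapse = ", ")),
    paste0("r_version: ", R.version.string)
  )
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(outdir)
}
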