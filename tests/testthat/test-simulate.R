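test_that("the RK4 step reproduces exponential decay to high order", {
  # one hourly step of y' = -y
  # local truncation error ~ dt^5/120 = 1.05e-9 at dt = 1/24
  y1 <- rk4_step(1, function(y) -y, 1 / 24)
  expect_lt(abs(y1 - exp(-1 / 24)) / exp(-1 / 24), 1e-8)
  # fourth-order convergence: halving dt cuts the error ~16x
  integrate_to_1 <- function(dt) {
    y <- 1
    for (i in seq_len(round(1 / dt))) y <- rk4_step(y, function(y) -y, dt)
    abs(y - exp(-1))
  }
  e1 <- integrate_to_1(1 / 10)
  e2 <- integrate_to_1(1 / 20)
  expect_gt(e1 / e2, 12)
  expect_lt(e1 / e2, 20)
})

test_that("a first-order vadose sink integrates to the closed form", {
  d <- one_basin_descriptors(frac_meadow = 1)
  f <- constant_forcing(d, hours = 25, t_soil = 5) # alpha = 1
  sc <- tracer_with(
    vadose_rates = vadose_rate_table(
      k_nit = c(df = 0, cf = 0, ms = 0, ww = 0),
      k_min = c(df = 0, cf = 0, ms = 0, ww = 0),
      k_den = c(df = 0, cf = 0, ms = 0.1, ww = 0)
    )
  )
  init <- matrix(0, 1, 9, dimnames = list("X", riverN:::POOL_NAMES))
  init[1, "n_s"] <- 100
  sim <- simulate_watershed(f, sc, d,
    init = init, quiet = TRUE
  )
  got <- sim$states[25, 1, "n_s"] # after 24 hourly steps = 1 day
  expect_lt(abs(got - 100 * exp(-0.1)) / (100 * exp(-0.1)), 1e-8)
  # the ledger recorded exactly the integrated denitrification mass
  den <- sum(sim$ledger[1:24, 1, "denitrification_vadose.n"]) / 24
  expect_rel_equal(den, 100 * (1 - exp(-0.1)), tol = 1e-8)
})

test_that("nitrification and mineralization are zero-sum transfers", {
  d <- one_basin_descriptors(frac_meadow = 1)
  f <- constant_forcing(d, hours = 49, t_soil = 5)
  sc <- tracer_with(
    vadose_rates = vadose_rate_table(
      k_nit = c(df = 0, cf = 0, ms = 0.3, ww = 0),
      k_min = c(df = 0, cf = 0, ms = 0.2, ww = 0),
      k_den = c(df = 0, cf = 0, ms = 0, ww = 0)
    )
  )
  init <- matrix(0, 1, 9, dimnames = list("X", riverN:::POOL_NAMES))
  init[1, c("a_s", "n_s", "o_s")] <- c(40, 10, 50)
  sim <- simulate_watershed(f, sc, d, init = init, quiet = TRUE)
  totals <- apply(sim$states[, 1, c("a_s", "n_s", "o_s")], 1, sum)
  expect_lt(max(abs(totals - 100)) / 100, 1e-12)
  # mass moved o -> a -> n, never created
  expect_true(all(diff(sim$states[, 1, "o_s"]) < 0))
  expect_true(all(diff(sim$states[, 1, "n_s"]) > 0))
})

test_that("tracer-mode transport conserves nitrogen through the network", {
  f <- generate_forcing(forcing_config(seed = 21, n_years = 1))
  sim <- simulate_watershed(f, tracer_scenario(),
    duration_days = 60, quiet = TRUE
  )
  cl <- ledger_closure(sim)
  expect_equal(cl$sources_mol, 0)
  expect_equal(cl$sinks_mol, 0)
  total0 <- sum(sim$states[1, , ])
  total1 <- sum(sim$states[dim(sim$states)[1], , ])
  expect_lt(
    abs(total1 + cl$outlet_export_mol - total0) / total0, 1e-6
  )
})

test_that("simulations are deterministic and order-independent", {
  d <- east_river_subwatersheds()
  f <- generate_forcing(forcing_config(seed = 5, n_years = 1), d)
  s1 <- simulate_watershed(f, "C2", d, duration_days = 3, seed = 7,
    quiet = TRUE)
  s2 <- simulate_watershed(f, "C2", d, duration_days = 3, seed = 7,
    quiet = TRUE)
  expect_identical(s1$states, s2$states)
  expect_identical(s1$ledger, s2$ledger)
  # permuting descriptor declaration order changes nothing
  perm <- d[c(4, 1, 5, 3, 2), ]
  s3 <- simulate_watershed(f, "C2", perm, duration_days = 3, seed = 7,
    quiet = TRUE)
  expect_equal(s3$states, s1$states)
  # different fixation seed gives different vadose ammonium
  s4 <- simulate_watershed(f, "C2", d, duration_days = 3, seed = 8,
    quiet = TRUE)
  expect_false(identical(s4$states, s1$states))
})

test_that("run bookkeeping matches the requested window", {
  d <- two_basin_descriptors()
  f <- generate_forcing(forcing_config(seed = 2, n_years = 1), d)
  sim <- simulate_watershed(f, "C2", d, duration_days = 2, quiet = TRUE)
  expect_equal(length(sim$timestamps), 48)
  conc <- tidy(sim)
  expect_equal(nrow(conc), 48 * 2 * 9)
  expect_true(all(conc$uM >= 0))
  expect_error(
    simulate_watershed(f, "C2", d, duration_days = 4000, quiet = TRUE),
    "hourly steps"
  )
})

test_that("the sink limiter keeps pools non-negative in stiff scenarios", {
  d <- east_river_subwatersheds()
  f <- generate_forcing(forcing_config(seed = 3, n_years = 1), d)
  # C1 vadose rates times warm-season alpha give k dt >> 1
  sim <- suppressWarnings(
    simulate_watershed(f, "C1", d, duration_days = 20, quiet = TRUE)
  )
  expect_gte(min(sim$states), 0)
  expect_false(anyNA(sim$states))
  g <- glance(sim)
  expect_lt(g$closure_rel_error, 1e-6)
})

test_that("spin-up reaches the closed-form steady state of a linear pool", {
  d <- one_basin_descriptors() # all-deciduous unit basin
  d$frac_meadow <- 0
  d$frac_deciduous <- 1
  f <- constant_forcing(d, hours = 24 * 30, t_soil = 5)
  # DON source from constant litter, first-order mineralization sink
  sc <- tracer_with(
    litter = litter_params(
      deciduous = c(0.001, 0.001, 0.001), meadow = c(0, 0),
      willow = c(0, 0, 0), upsilon = 0
    ),
    vadose_rates = vadose_rate_table(
      k_nit = c(df = 1, cf = 0, ms = 0, ww = 0), # drain the NH4 produced
      k_min = c(df = 0.05, cf = 0, ms = 0, ww = 0),
      k_den = c(df = 1, cf = 0, ms = 0, ww = 0)
    )
  )
  sim <- simulate_watershed(f, sc, d,
    init = "spinup", spinup_days = 30, duration_days = 1, quiet = TRUE
  )
  S <- 0.001 * 1e6 / 14 # mol/day
  steady <- S / 0.05
  expect_lt(abs(sim$states[1, 1, "o_s"] - steady) / steady, 0.05)
  expect_lte(sim$log$spinup_drift, 0.01)
})

test_that("zero-dynamics spin-up converges immediately", {
  d <- one_basin_descriptors()
  f <- constant_forcing(d, hours = 24 * 30)
  sim <- simulate_watershed(f, tracer_scenario(), d,
    init = "spinup", spinup_days = 7, duration_days = 1, quiet = TRUE
  )
  expect_equal(sim$log$spinup_repeats, 1L)
  expect_equal(sim$log$spinup_drift, 0)
})

test_that("explicit initial pools are honored unchanged", {
  d <- one_basin_descriptors()
  f <- constant_forcing(d, hours = 48)
  init <- matrix(
    seq(10, 90, by = 10), 1, 9,
    dimnames = list("X", riverN:::POOL_NAMES)
  )
  sim <- simulate_watershed(f, tracer_scenario(), d, init = init,
    quiet = TRUE)
  expect_equal(sim$states[1, 1, ], init[1, ])
})

test_that("outputs round-trip through disk with a complete manifest", {
  d <- two_basin_descriptors()
  f <- generate_forcing(forcing_config(seed = 6, n_years = 1), d)
  sim <- simulate_watershed(f, "C2", d, duration_days = 1, seed = 31,
    quiet = TRUE)
  outdir <- withr::local_tempdir()
  write_outputs(sim, outdir)
  conc <- readr::read_csv(
    file.path(outdir, "concentrations.csv"),
    show_col_types = FALSE
  )
  expect_equal(nrow(conc), nrow(tidy(sim)))
  expect_equal(conc$uM, tidy(sim)$uM, tolerance = 1e-12)
  manifest <- readLines(file.path(outdir, "manifest.txt"))
  expect_true(any(grepl("seed: 31", manifest)))
  led <- readr::read_csv(file.path(outdir, "ledger.csv"),
    show_col_types = FALSE)
  expect_true(all(c("flux", "species", "mol_per_day") %in% names(led)))
})
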