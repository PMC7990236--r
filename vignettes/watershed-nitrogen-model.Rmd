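---
title: "A semi-distributed nitrogen box model for snowmelt watersheds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semi-distributed nitrogen box model for snowmelt watersheds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverN)
```

## The model

`riverN` simulates dissolved nitrogen — ammonium (NH~4~^+^), nitrate
(NO~3~^-^) and dissolved organic nitrogen (DON) — moving through a
mountain headwater catchment discretized into routed sub-watersheds.
Each sub-watershed carries three water compartments (vadose zone,
stream, groundwater), so the default five-catchment configuration tracks
45 nitrogen pools (in mol). All reactions are first-order except plant
uptake, which saturates (Monod kinetics). The model targets
oligotrophic, snowmelt-dominated systems underlain by nitrogen-rich
shale, where the open question is how much of the dissolved nitrogen
budget is geogenic (rock-derived) rather than atmospheric or recycled
through plants and grazing cattle.

### Hydrologic drivers

The nitrogen model never solves hydrology itself. It consumes hourly
tables of compartment storage volumes ($V_s$, $V_r$, $V_g$, m^3^), net
infiltration minus soil evapotranspiration, overland flow minus stream
evapotranspiration (both m^3^ hr^-1^, signed), and soil/air
temperatures — the kind of output a distributed
groundwater–land-surface model produces after spatial aggregation.
From these, `derive_hydro_fluxes()` back-calculates the
inter-compartment flows analytically:

$$Q_s = [\mathit{Infilt}-ET_s] - \frac{\Delta V_s}{\Delta t}, \qquad
  Q_g = \begin{cases}\beta\,Q_s - \Delta V_g/\Delta t & Q_s > 0\\
  Q_s - \Delta V_g/\Delta t & Q_s \le 0\end{cases}$$

$$Q_r = (1-\beta)\max(Q_s,0) + Q_g + [Q_q - ET_r]
  + \textstyle\sum Q_{r,\mathrm{up}} - \Delta V_r/\Delta t$$

where $\beta \in [0,1]$ is the seasonal baseflow index (the share of
draining vadose water routed to groundwater; $1-\beta$ is interflow).
Re-integrating these flows reproduces the input volume series exactly,
which the test suite verifies. Negative stream balances are floored at
zero with the deficit logged. Residence times $\tau_x = V_x/Q_x$ (days)
are marked undefined — not zero — whenever the corresponding flow is
non-positive. Water temperature is an affine function of air
temperature floored at 0 °C (`stream_temperature()`, default
$T_w = \max(0,\,3.5 + 0.62\,T_{air})$, a literature-range stand-in, not
a site regression); groundwater temperature is the watershed-wide mean
of soil temperatures.

### Nitrogen sources, sinks and transformations

Per sub-watershed $i$ with area $A_i$, shale fraction $\sigma_i$ and
land-cover fractions $\rho_c$ (deciduous `df`, coniferous `cf`, meadow
`ms`, willow `ww`; the remainder is barren with zero rates):

* **Wet deposition** — constant precipitation concentrations
  (defaults 0.011 mol m^-3^ NO~3~^-^, 0.0068 NH~4~^+^, DON from the
  25 %-of-TDN rule, i.e. $(0.011+0.0068)/3$) times the net water flux
  entering the compartment. The term is applied with its sign: when
  evapotranspiration exceeds infiltration it removes nitrogen at
  precipitation concentration. A `clamp_wet_deposition` switch floors
  it at zero for users who prefer a strictly non-negative source.
* **Dry deposition** — constant areal rates applied to the vadose
  zone. The shipped defaults are rescaled so that annual watershed
  totals match the monitoring record's reported annual sums (1.73×10^4^
  mol NO~3~^-^, 7.99×10^4^ NH~4~^+^, 3.24×10^4^ DON per year over the
  default 84.8 km^2^), because the record's printed areal rates
  (0.28 / 1.29 / 0.52 mol m^-2^ day^-1^) are dimensionally inconsistent
  with those totals by about six orders of magnitude while agreeing in
  their NH~4~:NO~3~ ratio — a constant unit slip. Both
  parameterizations are exposed.
* **Shale weathering** — constant areal fluxes $M_a, M_n, M_o$
  (mol m^-2^ day^-1^); 90 % enters the vadose zone scaled by
  $\sigma_i$ (saprolite), 10 % enters groundwater over the full area
  (fractured bedrock). A `mancos_area` mode scales the groundwater
  share by $\sigma_i$ as well.
* **Plant uptake** — Monod:
  $F = F_{max}\,N/(K_m V_s + N)$ with
  $F_{max} = \alpha A_i \sum_c F_{max,c}\,\rho_c$ and soil-temperature
  factor $\alpha = \vartheta_s^{(T_{soil}-5)/2}$, $\vartheta_s = 12$.
  The per-cover maxima and half-saturation constants shipped here are
  synthetic defaults with literature-plausible magnitudes (the original
  site-specific table is unpublished); every value is a parameter.
* **Vadose transformations** — nitrification (NH~4~^+^→NO~3~^-^), net
  mineralization (DON→NH~4~^+^) and denitrification (NO~3~^-^ loss)
  with cover-weighted first-order constants
  $k = \alpha \sum_c k_c\rho_c$. The area factor that would make a
  rate constant dimensionally inconsistent is deliberately not applied
  here (it is required, and kept, in the uptake maxima).
* **In-stream reactions** — first-order mineralization (default
  1.5 day^-1^ at 20 °C, reflecting fast breakdown of fresh terrestrial
  organic matter), nitrification, biological uptake (NH~4~^+^ and
  NO~3~^-^ only) and denitrification, all corrected as
  $k = k_{20}\,\vartheta_r^{T_w - 20}$ with $\vartheta_r = 1.07$.
  Stream export is $N/\tau_r$; upstream reaches feed their export into
  the receiving reach within the same integration stage, so routing
  adds no artificial one-step lag.
* **Groundwater** — exchange with the vadose zone at donor
  concentration ($\beta Q_s N_s/V_s$ downward when $Q_s>0$;
  $Q_s N_g/V_g$ upward when $Q_s<0$), exchange with the stream
  ($N_g/\tau_g$ when discharging, stream-concentration recharge
  $(N_r/V_r)\,Q_g$ when losing), and denitrification
  $k = k_{den,max}\,\vartheta_g^{3.8-T_{gw}}$ ($\vartheta_g = 0.3$)
  gated on vadose outflow exceeding 10^5^ m^3^ day^-1^ — rapid
  recharge, water-table rise, near-surface anoxia.
* **Litterfall** — piecewise-constant daily DON release per cover
  (three day-of-year intervals for deciduous/willow, two for meadow;
  leap-aware), plus a spruce term driven by gross primary productivity,
  $GPP = 1.51/(0.2375 + e^{-0.21 T_{air}})$ and
  $F = \upsilon\, 0.0057\, e^{-0.293\,GPP}$ (g N m^-2^ day^-1^,
  converted at 14 g mol^-1^). Optional mean-preserving multiplicative
  jitter (U[0.5, 1.5]) emulates day-to-day litterfall variability and
  is off by default for reproducibility.
* **Cattle** — $F = n_{cows} G_i (L_{dung} + L_{urine})$ with 500 head
  at 8.6 + 15 mol cow^-1^ day^-1^ and the local rotation (full herd in
  the lowest catchment mid-July to early September, then split across
  the upper catchments until mid-October).
* **Fixation** — meadow nitrogen fixers (1 % of meadow cover) add
  NH~4~^+^ at an areal rate drawn uniformly in [10^-8^, 10^-4^]
  mol m^-2^ day^-1^, one draw per sub-watershed per day, only while
  soil is above freezing. The uniform law is a deliberate, simple
  reading of "a random number between" the bounds.

Two of the forms above are dimensional corrections of common
formulations: advection out of the vadose zone is flow × concentration
($Q_s N/V_s$), consistent with $\tau_s = V_s/Q_s$ appearing in the
interflow expression, and stream-to-groundwater recharge is likewise
concentration × flow. Both choices are what conservation requires; the
alternative (flow × pool mass) has units of mol m^3^ day^-1^.

## Numerical scheme

The 45-pool system is advanced with classical fourth-order Runge–Kutta
at an hourly step ($\Delta t = 1/24$ day; all rate parameters are
day^-1^). Forcing is held piecewise-constant over each hour. The test
suite verifies fourth-order convergence and agreement with analytic
exponential decay to 10^-8^ relative for $k\Delta t \le 0.1$ (the local
truncation error of one hourly step of $y'=-y$ is
$\Delta t^5/120 \approx 10^{-9}$).

**Stiffness.** $\vartheta_s = 12$ makes the vadose temperature factor
explode at warm soils ($\alpha = 12^{(T-5)/2}$ is ~270 at 9.5 °C), so
effective rate constants can reach hundreds per day and $k\Delta t \gg
1$. The model keeps the formulation verbatim (a warning fires when
$\alpha > 10^6$) and relies on a **proportional sink limiter**: inside
every RK4 stage, if the combined sinks of a pool would drive it
negative over $\Delta t$, all of that pool's sink fluxes are scaled by
a common factor so the projected end-of-step pool is exactly zero.
Scaling follows the donor pool, so a limited nitrification flux is
reduced identically on its NH~4~^+^ (loss) and NO~3~^-^ (gain) sides
and transfers stay zero-sum. Pools therefore saturate at zero instead
of oscillating; the dynamics there are a projection, not an accurate
stiff solve, which is acceptable because parameters are not constrained
to resolve sub-daily kinetics. Limiter scales are computed once per
stage from the unscaled fluxes; because a scaled-down upstream export
also reduces a recipient's source, a final end-of-step clamp zeroes any
residual negative pool (typically round-off-sized) and books the
correction into the ledger, so mass accounting stays exact. Both event
counts are reported in the run log.

**Flux ledger.** Every named flux is accumulated with the same RK4
stage weights (1/6, 1/3, 1/3, 1/6) as the state. Consequently
ledger-integrated mass change equals the state change to round-off —
the suite checks ≤10^-6^ relative, and observed closure is ~10^-16^.
Transfers are recorded in their donor-species column; signed exchange
fluxes keep their sign.

**Initialization.** Stream pools start from supplied or default
concentrations (defaults 1/5/4 µM NH~4~^+^/NO~3~^-^/DON, the order of
magnitude measured in such streams; bias decays within a few residence
times). Subsurface pools either start from defaults (vadose 10/20/50,
groundwater 20/20/100 µM), from explicit values, or from a winter
spin-up: the first 90 days of forcing are integrated repeatedly until
no subsurface pool changes by more than 1 % over a repeat (cap 20;
non-convergence warns with the final drift). The stopping rule is this
package's reproducible replacement for manual iterative adjustment.

## The synthetic forcing generator

Running the nitrogen model requires hydrologic forcing that is not
publicly distributable, so `generate_forcing()` synthesizes it with the
statistical features that matter to nitrogen routing in this regime:

* near-zero infiltration under winter snowpack, a Gaussian
  March–June snowmelt pulse carrying most of the annual water input
  (the generated share of positive infiltration in March–June is
  ~0.9, and is asserted ≥ 0.5),
* negative net infiltration (evapotranspiration) in late summer,
  Poisson-timed monsoon storm events in August–October,
* storage volumes produced by routing that water through linear
  vadose → groundwater → stream reservoirs (default residence scales
  1/0.025, 1/0.01 and 1/0.5 days), so emitted volumes and fluxes are
  mutually consistent and back-calculation recovers the generating
  flows exactly,
* seasonal air/soil temperature sinusoids with diel variation on air
  temperature; soil temperature is clamped to [-5, 20] °C.

It does **not** emulate: spatially correlated storm cells, rain-on-snow
events, inter-annual snowpack extremes, water-table-depth feedback on
weathering, hysteresis in storage–discharge relations, or measurement
noise in volumes. Tests passing on this forcing therefore demonstrate
the correctness and conservation of the *model machinery*, not
predictive skill for any real catchment; calibrated concentrations on
real forcing are out of scope here. All amplitudes are areal rates
(m day^-1^) scaled by catchment area, and a seed fully determines the
output without touching the caller's RNG stream.

## Scenarios, budgets and calibration checks

`load_scenario()` packages six parameter sets spanning regions of the
parameter space that fit the same stream nitrate record about equally
well (an equifinality ensemble): subsurface-dominated (`C1`),
stream-dominated (`C2`, the most plausible), mixed with maximal
weathering (`C3`), two no-shale counterparts (`NM1`, `NM2`) and a
no-cattle variant (`NC`). Each piece is independently overridable.

`annual_budget()` aggregates a water year (October–September) of the
ledger into source shares (wet/dry deposition, weathering, fixation,
litter, cattle) and sink shares (plant uptake, subsurface
denitrification, in-stream loss = in-stream denitrification plus
uptake, downstream export). "New" nitrogen defaults to deposition +
weathering + fixation — everything not liberated from plants or cattle;
the set is an argument because fixation's classification is a
convention. Because weathering is constant in time, its ledger total
has a closed form, checked exactly in the tests.
`balance_checks()` implements the two manual-calibration rules: litter
plus cattle within ±10 % of plant uptake, and total sinks within ±10 %
of total sources; zero denominators are indeterminate rather than
passes. `rmse_concentration()` scores modeled against observed
concentrations (µM) by nearest-timestamp matching within a tolerance
(default 1 h), using instantaneous model values — concentrations, not
fluxes, because discharge variability dwarfs concentration signal in
this regime.

## Problem sizes and tolerances

The shipped tests integrate 1–90 day windows on one-, two- and
five-catchment configurations; the acceptance script runs a full
simulated tracer year plus a 120-day reactive run, all on synthetic
forcing — sizes chosen so the whole suite completes in minutes on a
single core while still exercising every seasonal regime (snowmelt
onset, monsoon, winter baseflow). Conservation checks use 10^-6^
relative tolerance (observed ~10^-16^), closed-form comparisons 10^-8^
to 10^-12^, and spin-up steady-state agreement 5 %.

## Known limitations

* The sink limiter makes warm-season vadose kinetics a projection onto
  the non-negative orthant rather than a resolved stiff solve; with
  $\vartheta_s = 12$ this is unavoidable at an hourly explicit step.
* Gaseous speciation (N~2~ vs N~2~O), DNRA, sorption, particulate
  nitrogen and isotope tracing are out of scope.
* The groundwater denitrification gate is a binary threshold on vadose
  outflow; real anoxia develops continuously.
* Baseflow indices, stream-temperature coefficients and uptake
  parameters ship as documented placeholders/synthetic defaults and
  should be replaced with site values for any real application.
* No automated calibration: the scenario ensemble is the uncertainty
  statement.
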