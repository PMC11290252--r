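---
title: "Modelling the evolution of diapause-exit phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of diapause-exit phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copevolve)
```

`copevolve` simulates the multi-generation evolution of the diapause-exit
date in a high-latitude copepod population. This vignette explains the
model, the choices behind its tunable parameters, what the synthetic
forcing does and does not emulate, and the numerical conventions a user
should know before trusting (or extending) the results.

## The trait and its realization

The heritable trait is a pair: the mean diapause-exit day on a 10-day grid
(Julian days 50–200, 16 values) and a phenotypic-variance standard
deviation SDPV ∈ {0, 10, 20, 30, 40} days. An individual's realized exit
day is drawn once, at the egg stage: mean + a N(0, SDPV²) deviate rounded
to the nearest 10-day setting (ties away from zero) and clamped to the
grid range. Clamping, rather than redrawing or discarding, keeps every
realized day a valid lookup key and leaves the trait's realized
distribution well defined at the grid edges; `exit_day_weights()` gives
the exact discretized-Gaussian mass that results, and the test suite
checks the sampler against it. Inheritance is clonal and exact — no
mutation, recombination or environmental cueing — so all change in trait
frequencies is selection plus resampling noise.

## The bioenergetic core

Each (spawn day, exit day, year) combination maps to one deterministic
daily life history, integrated once and stored. The life cycle has six
phases: non-feeding egg/early nauplius (phase 1, a temperature-dependent
timer of 7 days at 10 °C with Q10 = 2), feeding growth (phase 2), growth
plus lipid deposition (phase 3) until the diapause-entry thresholds are
met (6.5 μmol C structure and 7.52 μmol C lipid, 80 % of 9.4), diapause at
depth (phase 4), a fixed 14-day gonad-maturation period (phase 5), and the
income-breeding adult (phase 6). Transitions 4→5 and 5→6 are calendar
commitments derived from the realized exit day; if an individual has not
reached diapause when its phase-5 start day arrives, the trajectory is
recorded as non-viable (zero fitness), not an error.

The carbon budget is deliberately simple: assimilated ingestion (Holling
type III on summed food, efficiency 0.7) minus basal metabolism, both as
biomass-specific rates on structural carbon with Q10 = 2. The full
stoichiometric machinery of larger copepod models (carbon–nitrogen
co-limitation, biomass turnover, specific dynamic action) lives behind the
same trajectory interface and could replace this core without touching the
population model, which consumes only daily phase/biomass/egg records.
Parameter defaults and their reasoning:

* `graz_imax_ref = 0.3 d⁻¹`, `graz_half_sat = 1.5 mmol C m⁻³`,
  `basal_metab_ref = 0.03 d⁻¹` (all at 9 °C). Together these give an
  egg-to-diapause development time of roughly 50–70 days in bloom
  conditions — the requirement that a spring-spawned egg reliably reaches
  the diapause threshold within one growing season, including in the cold,
  late year of the decade preset, pins these magnitudes far more tightly
  than any one of them individually.
* Ingestion scales linearly with structural biomass. A size-independent
  absolute rate cannot serve both a 0.023 μmol C egg and a 6.5 μmol C
  adult; linear scaling is the simplest allometry consistent with a single
  specific-rate parameter.
* `gonad_lipid_frac = 0.25`: a quarter of the diapause lipid store is
  consumed as a provisioning cost during phase 5, on top of (unsuppressed)
  deep-water metabolism. This leaves a post-exit adult roughly a two- to
  three-week starvation buffer (lipid first, then structural catabolism
  down to `starve_structure_frac = 0.7` of peak structure). That buffer
  is the load-bearing quantity for the whole study: it sets how many days
  before the bloom an adult can afford to surface, and therefore how
  lethal an anomalously late bloom is to early-exiting phenotypes.
  Without a gonad cost the untouched lipid store would buy months of
  fasting and bloom-timing variability would exert almost no selection.
* `egg_carbon = 0.023 μmol C`. Only relative fitness matters to
  selection; this scales absolute fecundity (and makes it high, ~2000
  eggs per female in good years) without moving trait optima.
* Eggs spawned outside Julian days 50–300 are discarded as non-viable
  (winter food scarcity); spawn days are binned to the nearest 5-day bin,
  ties downward.

## Predation mortality

Death by predation is a daily Bernoulli draw. Surface stages use
m(T) = m(T_ref)·exp(0.214·(T − T_ref)) with T_ref = 9 °C — the
growing-season mean SST of the default forcing, so the reference rates
apply mid-season — with m₁ = 0.03 d⁻¹ (phases 1–3) and m₃ = 0.02 d⁻¹
(phase 6). The deep phases use a flat m₂ = 0.002 d⁻¹: the deep-water
temperature is constant, so temperature scaling there would be a no-op,
and dark water is a refuge from visual predators regardless. The
exponential coefficient corresponds to a Q10 of ≈ 8.5, which makes the
*seasonality* of predation — low in the cold early spring, high in
summer — the dominant top-down selective gradient. Sensitivity presets
replace the seasonal scaling with flat reference rates, or multiply all
probabilities by 1.5 or 2 (capped at 1).

The engine never draws day-by-day per individual. For each stored
trajectory it computes the exact death-day distribution
(P(die day i) = pᵢ·Π_{j<i}(1 − pⱼ)) and samples whole cells of
exchangeable individuals with one multinomial — distributionally
identical to the per-day draws, which the tests verify against a
brute-force Bernoulli oracle (Kolmogorov–Smirnov at n = 10⁵).

## The selection engine

A generation starts as a cohort of eggs laid out on the trait × spawn-bin
grid (the full design: 80 × 51 = 4080 cells). For each cell the engine
realizes exit days from the trait's discretized Gaussian, samples each
sub-cell's fate, credits surviving mothers' daily eggs (with the maternal
trait) to next year's spawn bins, and then resamples the offspring pool to
a fixed sub-population size by largest-remainder proportional allocation —
exactly n_pop eggs whose cell frequencies match the offspring distribution
to within 1/n_pop, with randomness only in remainder ties. Convergence is
strict fixation of a single trait pair; a guard reports (rather than
hides) non-convergence after `max_generations`. Because proportional
resampling preserves even one-egg remainders, the final approach to strict
fixation can be slow at large n_pop; runs that terminate at the guard are
summarized by their dominant trait, which in practice is at > 0.84
frequency by then. After convergence an analysis pass of one full
sequence of the forcing (10 generations for the decade) records per-cell
fates, arrivals, deaths and egg schedules for the phenology diagnostics.

Reproducibility: one seeded RNG stream per run, with cells visited in a
fixed grid order, makes every run a pure function of (config, seed). The
per-individual counter-based substreams that would make results invariant
to arbitrary visit order were not needed: the order is deterministic, and
individuals within a cell are exchangeable.

## The expected-fitness oracle

Selection under frequency-preserving resampling renormalizes all traits by
the same factor each generation, so trait frequencies evolve like
independent branching processes and the trait with the largest asymptotic
growth rate fixes. For each trait and year the engine's fate tables give a
51 × 51 spawn-bin projection matrix (expected viable eggs in each next-year
bin per egg in each bin, combining exit realization, survival to adulthood
and the egg schedule with no sampling). The oracle growth rate is the
dominant eigenvalue of that matrix for repeat-year forcing, or the
per-cycle geometric growth of the ten-matrix product for the decade. A
simpler bin-averaged expected-offspring count (`expected_offspring_per_egg`)
is also exposed, but the eigenvalue is the quantity selection actually
maximizes — the bin distribution of a lineage converges to the matrix's
leading eigenvector, not to the uniform distribution. The engine is
validated against the oracle: in decisive scenarios the stochastic run
fixes the oracle's argmax.

## Synthetic forcing: what it emulates, and what it does not

The forcing generator produces the *structure* of a seasonal subarctic
station: total food as a winter baseline (0.1 mmol C m⁻³) plus an
asymmetric truncated-Gaussian bloom pulse (exactly baseline outside the
bloom window, exactly the peak at the peak day, a slower autumn decline
than spring rise), split into fixed diatom/non-diatom/microzooplankton/
detritus fractions, and a sinusoidal SST cycle. Defaults put the bloom
peak at 6 mmol C m⁻³ and the SST cycle (3.2–10.7 °C, peaking day 215) so
that the growing-season mean is ≈ 9 °C — consistent with the mortality
reference — and so that the spring warm-up, which drives the seasonal
predation gradient, happens across the spawning window.

The decade preset encodes ten years whose bloom peaks span days 140
(year 4, earliest) to 170 (year 2, latest). Two further dimensions vary
interannually, because both are needed for bet-hedging to have anything to
work on:

* **Onset steepness.** The day total food first reaches 2 mmol C m⁻³
  varies far more than the peak day (≈ day 96 to ≈ day 160): early-bloom
  years ramp up gradually from late winter, late years rise steeply. The
  single-year ("repeat-year") optima therefore span roughly days 80–150,
  tracking onset approximately 1:1.
* **Season length.** Early-bloom years have short post-peak tails,
  late-bloom years long ones. Short seasons are what punish late-exiting
  phenotypes (their eggs cannot finish development before the autumn food
  collapse); without this, a single sufficiently late fixed exit date is
  safe everywhere and phenotypic variance never pays.

Year 2 is the anomalous year: the latest, steepest bloom plus a cold
spring with a delayed SST peak. Adults surfacing before roughly day 120
in that year exhaust their reserves before any food arrives; the year
zeroes the early-exit phenotypes outright.

What the generator does *not* emulate: mixed-layer physics, advection
past a fixed station, multi-pulse blooms, trends or autocorrelation across
years (the decade repeats exactly), and any food–predator feedback. The
tests therefore demonstrate that the selection machinery produces the
expected evolutionary responses *to forcing with these statistical
features* — they are not a hindcast of any particular station or decade,
and the absolute fecundities and survivorships carry no empirical weight.

## What the experiments show

With the defaults above, the deterministic oracle and the stochastic
engine agree on the qualitative pattern: repeat-year worlds select a
zero-variance exit date tracking the bloom onset; the variable decade
selects a compromise — exit around day 100, later than the most common
single-year optimum, with SDPV = 20 (the engine's replicate ensembles fix
(100, 20)) — an intermediate variance, since too little cannot cover the
anomalous year and too much wastes phenotypes in ordinary years.
Forcing SDPV = 0 pushes the fixed exit later (day 110). Removing the
seasonality of predation delays exit by about 10 days (the early-season
refuge premium on early eggs disappears), while scaling seasonal predation
by 1.5 or 2 leaves the optimum in place — the timing signal, not the
absolute intensity, is what matters.

## Numerical conventions and scale

Days are 1-based Julian days in 365-day years (no leap days). Phase-1
durations round up to whole days. Five-day forcing tables are linearly
interpolated to daily. Trajectory stores round-trip through CSV bit-exactly
(17 significant digits). Multi-year sequences carry a two-year cyclic
lookahead so late-spawned trajectories always have forcing to read.

Sub-population sizing follows the design of the study: a large founding
cohort (100 eggs per trait × bin cell, 408,000 in the full design) for the
first 20 generations, then a reduced size. The packaged test and
acceptance runs use scaled-down cohorts chosen for their purpose: 2
eggs/cell ("desk" preset) where the point is that even a small stochastic
run finds the optimum of a decisive landscape, and 50 eggs/cell for the
interannual ensembles, where the fitness ridge between neighbouring traits
is a few percent and founder noise at 2 eggs/cell would otherwise dominate
the verdict — the same reasoning that motivates the large founding cohort
in the full design. Fate tables are recomputed per mortality preset; the
trajectory store is mortality-independent and shared across sensitivity
experiments.

## Known limitations

The carbon-only bioenergetic core is a stand-in calibrated to reproduce
life-history *timing*, not measured rates; capital breeding, the one-year
(no-diapause) life cycle, diel vertical migration, explicit sexes, density
dependence and mutation are all outside scope. Strict fixation is the only
convergence notion; nearly-neutral trait pairs can keep a small remainder
alive for many generations under proportional resampling. The oracle
assumes the forcing cycle repeats exactly; it has no notion of
non-stationary environments.
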