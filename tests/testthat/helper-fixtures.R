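# Shared fixtures, built once per test run. Scaled-down grids keep store
# builds fast; the full-grid stores used by the acceptance tests are built
# lazily and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# small repeat-year world: every 4th spawn bin, full 16-exit grid
small_bins <- function() seq(50L, 300L, by = 20L)

fixture_forcing <- function(peak = 150) {
  key <- paste0("forcing_", peak)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- assemble_sequence(list(repeat_year_preset(peak)))
  .fixtures[[key]]
}

fixture_store <- function(peak = 150) {
  key <- paste0("store_", peak)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- build_lookup(fixture_forcing(peak),
                                     spawn_bins = small_bins())
  .fixtures[[key]]
}

fixture_ftab <- function(peak = 150, preset = "default") {
  key <- paste0("ftab_", peak, "_", preset)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- build_fate_tables(fixture_store(peak),
                                          fixture_forcing(peak),
                                          mortality_preset(preset))
  .fixtures[[key]]
}

# full-grid decade world for the interannual acceptance checks
fixture_decade_forcing <- function() {
  if (is.null(.fixtures$decade_forcing))
    .fixtures$decade_forcing <- assemble_sequence(decade_preset())
  .fixtures$decade_forcing
}

fixture_decade_store <- function() {
  if (is.null(.fixtures$decade_store))
    .fixtures$decade_store <- build_lookup(fixture_decade_forcing())
  .fixtures$decade_store
}

fixture_decade_ftab <- function(preset = "default") {
  key <- paste0("decade_ftab_", preset)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- build_fate_tables(fixture_decade_store(),
                                          fixture_decade_forcing(),
                                          mortality_preset(preset))
  .fixtures[[key]]
}

# full-grid single repeat-year world (all 51 bins, 16 exits)
fixture_ry_full <- function(peak = 150, anomalous = FALSE) {
  key <- paste0("ryfull_", peak, "_", anomalous)
  if (is.null(.fixtures[[key]])) {
    f <- assemble_sequence(list(repeat_year_preset(peak, anomalous)))
    st <- build_lookup(f)
    .fixtures[[key]] <- list(forcing = f, store = st,
                             ftab = build_fate_tables(st, f))
  }
  .fixtures[[key]]
}

# run an ensemble at a given per-cell founding density and return the
# dominant (converged) trait of each seed
ensemble_traits <- function(ftab, seeds, per_cell = 50L, forced_sdpv = NULL,
                            max_generations = 300L) {
  n_traits <- if (is.null(forced_sdpv)) 80L else 16L
  n_cells <- n_traits * length(ftab$spawn_bins)
  do.call(rbind, lapply(seeds, function(s) {
    cfg <- run_config(n_pop_init = per_cell * n_cells,
                      n_pop_reduced = as.integer(ceiling(per_cell / 4) * n_cells),
                      max_generations = max_generations, seed = s,
                      convergence_extra_years = 1L,
                      forced_sdpv = forced_sdpv)
    r <- suppressWarnings(run_to_convergence(cfg, ftab))
    data.frame(seed = s, exit_mean = r$trait$exit_mean, sdpv = r$trait$sdpv,
               converged = r$converged)
  }))
}

modal_value <- function(x) {
  tab <- table(x)
  # ties broken toward the smallest value
  as.numeric(names(tab)[tab == max(tab)][1L])
}

# constant-environment forcing: flat food and SST all year
flat_forcing <- function(food_total = 6, sst = 10, n_days = 365 * 3 + 730) {
  food <- matrix(food_total / 4, n_days, 4)
  copevolve:::new_forcing_series(food, rep(sst, n_days),
                                 deep_temperature = 4, n_years = 1L)
}

# a synthetic fate-tables object with hand-set cells, for engine tests that
# need exact control over fates and fecundity
synthetic_ftab <- function(cells, spawn_bins, exit_grid, years = 1L) {
  tables <- lapply(years, function(y)
    lapply(seq_along(spawn_bins), function(bi)
      lapply(seq_along(exit_grid), function(ei)
        cells(y, bi, ei))))
  structure(list(years = years, spawn_bins = spawn_bins,
                 exit_grid = exit_grid, tables = tables,
                 mp = mortality_params()),
            class = "fate_tables")
}

# a fate cell in which every egg survives to adulthood and deterministically
# produces `eggs` offspring into spawn-bin index `bin_i` (no adult death)
sure_cell <- function(bin_i, eggs, n_bins) {
  expected <- numeric(n_bins)
  expected[bin_i] <- eggs
  list(probs = c(rep(0, 5), 0, 1), has_adult = TRUE, L = 1L,
       p_adult = 1, eggs6 = eggs, bin6 = bin_i, doy6 = 150L,
       arrival_doy = 100L, adult_starves = FALSE, starve_doy = NA_integer_,
       expected_bin = expected, spawn_doy = 0L, exit_doy = 0L)
}
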