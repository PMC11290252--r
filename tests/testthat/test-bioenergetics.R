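test_that("phase-1 duration follows the Q10 law with ceiling rounding", {
  p <- bio_params()
  expect_equal(phase1_duration(10, p), 7)
  expect_equal(phase1_duration(20, p), 4)   # 3.5 rounded up
  expect_equal(phase1_duration(0, p), 14)
  expect_error(phase1_duration(NA_real_, p))
})

test_that("ingestion follows a Holling III response with Q10 scaling", {
  p <- bio_params()
  expect_equal(grazing_rate(c(0, 0, 0, 0), 10, p), 0)
  # half-saturation point: half the temperature-scaled maximum
  k <- p$graz_half_sat
  imax10 <- p$graz_imax_ref * p$graz_q10^((10 - p$t_ref_bio) / 10)
  expect_equal(grazing_rate(k, 10, p), imax10 / 2, tolerance = 1e-12)
  # approach to the asymptote: within 1% at S = 10k
  expect_gt(grazing_rate(10 * k, 10, p), 0.99 * imax10)
  # specific rate scales linearly with structural biomass
  expect_equal(grazing_rate(k, 10, p, structure_c = 6.5),
               6.5 * grazing_rate(k, 10, p), tolerance = 1e-12)
  # no feeding in the non-feeding phases
  for (ph in c(1L, 4L, 5L)) expect_equal(grazing_rate(5, 10, p, phase = ph), 0)
  expect_error(grazing_rate(-1, 10, p), "negative food")
})

test_that("a single diapause day respires suppressed lipid at deep temperature", {
  p <- bio_params()
  st <- initial_state(p)
  st$phase <- 4L; st$structure_c <- 6.5; st$lipid_c <- 7.52
  st$max_structure <- 6.5
  out <- step_individual(st, list(food = 0, sst = 9, deep_t = 4), p)
  expected_resp <- p$diapause_metab_factor * p$basal_metab_ref *
    p$metab_q10^((4 - p$t_ref_bio) / 10) * 6.5
  expect_equal(out$lipid_c, 7.52 - expected_resp, tolerance = 1e-12)
  expect_equal(out$phase, 4L)
  expect_true(out$alive)
  expect_equal(out$structure_c, 6.5)
})

test_that("phase 3 transitions to diapause when both thresholds are met", {
  p <- bio_params()
  st <- initial_state(p)
  st$phase <- 3L; st$structure_c <- 6.5; st$lipid_c <- 7.5
  st$max_structure <- 6.5
  # ample food: the day's net gain tops lipid past the threshold
  out <- step_individual(st, list(food = 20, sst = 9), p)
  expect_gte(out$lipid_c, p$lipid_at_diapause)
  expect_equal(out$phase, 4L)
})

test_that("an adult with exhausted reserves and no food starves", {
  p <- bio_params()
  st <- initial_state(p)
  st$phase <- 6L; st$structure_c <- 6.5; st$lipid_c <- 0.05
  st$max_structure <- 6.5
  days <- 0L
  while (st$alive && days < 100L) {
    st <- step_individual(st, list(food = 0, sst = 9), p)
    expect_equal(st$eggs_today, 0L)
    days <- days + 1L
  }
  expect_false(st$alive)
  expect_true(st$starved)
  expect_lt(days, 30L)  # a starving adult does not linger for a season
})

test_that("trajectories are translation-invariant under repeat-year forcing", {
  f <- assemble_sequence(list(repeat_year_preset(150)), n_passes = 2L)
  t1 <- simulate_trajectory(1, 130, 110, f)
  t2 <- simulate_trajectory(2, 130, 110, f)
  expect_equal(t2$day, t1$day + 365L)
  expect_equal(t2$phase, t1$phase)
  expect_equal(t2$structure_c, t1$structure_c)
  expect_equal(t2$lipid_c, t1$lipid_c)
  expect_equal(t2$eggs, t1$eggs)
})

test_that("zero food everywhere kills the egg in early development", {
  f0 <- flat_forcing(food_total = 0, sst = 8)
  tr <- simulate_trajectory(1, 130, 110, f0)
  expect_false(tr$reached_adult)
  expect_false(is.na(tr$starvation_day))
  expect_equal(max(tr$phase), 2L)
  expect_equal(sum(tr$eggs), 0L)
})

test_that("ample constant food carries an egg through all six phases", {
  f6 <- flat_forcing(food_total = 6, sst = 10)
  tr <- simulate_trajectory(1, 130, 110, f6)
  expect_true(tr$reached_adult)
  expect_equal(sort(unique(tr$phase)), 1:6)
  expect_gt(sum(tr$eggs), 0L)
  # diapause entry lands at total biomass 14.0 within one day's growth
  i4 <- match(4L, tr$phase)
  total_at_entry <- tr$structure_c[i4] + tr$lipid_c[i4]
  expect_lt(abs(total_at_entry - 14.02), 1)
  expect_gte(total_at_entry, 14.02 - 1e-9)
  # committed timing: phase 5 starts 14 days before exit, phase 6 on exit day
  expect_equal(tr$day[match(5L, tr$phase)], tr$exit_day - 14L)
  expect_equal(tr$day[match(6L, tr$phase)], tr$exit_day)
})

test_that("an exit date before diapause readiness yields a non-viable trajectory", {
  # barely-positive growth: still a juvenile when the exit commitment falls
  slow <- flat_forcing(food_total = 0.9, sst = 9)
  tr <- simulate_trajectory(1, 130, 50, slow)
  expect_false(tr$viable)
  expect_false(tr$reached_adult)
  expect_equal(sum(tr$eggs), 0L)
  # spawned too late in the season: starves in development, zero fitness
  late <- simulate_trajectory(1, 300, 50, fixture_forcing())
  expect_false(late$reached_adult)
  expect_false(is.na(late$starvation_day))
  expect_equal(sum(late$eggs), 0L)
})

test_that("trajectory invariants hold across the whole lookup grid", {
  store <- fixture_store()
  for (b in store$spawn_bins) {
    for (e in store$exit_grid) {
      tr <- lookup_trajectory(store, 1, b, e)
      expect_true(all(diff(tr$phase) >= 0))
      expect_true(all(tr$structure_c >= 0 & tr$lipid_c >= -1e-12))
      expect_true(all(tr$eggs[tr$phase != 6L] == 0L))
      expect_equal(tr$deep, tr$phase %in% c(4L, 5L))
      # lipid rises only while accumulating reserves (phase 3; the entry
      # day into diapause is labelled with its end-of-day phase 4)
      dl <- diff(tr$lipid_c)
      rising <- which(dl > 1e-12)
      expect_true(all(tr$phase[rising + 1L] %in% c(3L, 4L)))
      expect_true(all(tr$phase[rising] %in% c(2L, 3L)))
      expect_lte(length(tr$day), bio_params()$max_lifespan_days)
    }
  }
})

test_that("the lookup store covers the grid and retrieves exact trajectories", {
  f <- fixture_forcing()
  store <- fixture_store()
  expect_equal(length(ls(store$trajectories)),
               length(store$spawn_bins) * length(store$exit_grid))
  tr <- lookup_trajectory(store, 1, 130, 110)
  fresh <- simulate_trajectory(1, 130, 110, f)
  expect_equal(tr$structure_c, fresh$structure_c)
  expect_equal(tr$eggs, fresh$eggs)
  expect_error(lookup_trajectory(store, 1, 130, 115), "y1_b130_e115")
  expect_error(build_lookup(f, spawn_bins = integer()), "empty grid")
})

test_that("a full 51 x 16 single-year grid stores 816 trajectories", {
  # the grid product that the population engine relies on
  expect_equal(length(spawn_bin_grid()) * length(exit_day_grid()), 816L)
  expect_equal(length(spawn_bin_grid()), 51L)
  expect_equal(length(exit_day_grid()), 16L)
})

test_that("the trajectory store CSV round-trip is bit-exact", {
  store <- fixture_store()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_store(store, path)
  store2 <- read_trajectory_store(path)
  expect_equal(sort(ls(store2$trajectories)), sort(ls(store$trajectories)))
  for (k in c("y1_b130_e110", "y1_b290_e60", "y1_b50_e200")) {
    a <- store$trajectories[[k]]; b <- store2$trajectories[[k]]
    expect_identical(b$structure_c, a$structure_c)
    expect_identical(b$lipid_c, a$lipid_c)
    expect_equal(b$phase, a$phase)
    expect_equal(b$eggs, a$eggs)
    expect_equal(b$starvation_day, a$starvation_day)
    expect_equal(b$reached_adult, a$reached_adult)
  }
})
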