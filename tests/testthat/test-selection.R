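test_that("the founding cohort allocates eggs uniformly over the grid", {
  counts <- init_population(408000L)
  expect_equal(dim(counts), c(80L, 51L))
  expect_true(all(counts == 100L))
  expect_equal(sum(counts), 408000L)
  expect_true(all(init_population(4080L) == 1L))
  expect_error(init_population(4081L), "not divisible")
  # restricted grid: 16 traits with SDPV forced off
  c0 <- init_population(1632L, traits = trait_grid(forced_sdpv = 0))
  expect_equal(dim(c0), c(16L, 51L))
  expect_true(all(c0 == 2L))
})

test_that("resampling is exactly proportional where counts divide evenly", {
  one <- matrix(c(0, 12, 0), 3, 1)
  expect_equal(as.vector(resample_offspring(one, 1000L)), c(0L, 1000L, 0L))
  half <- matrix(c(300, 300), 2, 1)
  expect_equal(as.vector(resample_offspring(half, 1000L)), c(500L, 500L))
})

test_that("largest-remainder allocation splits ties randomly", {
  thirds <- matrix(c(1, 1, 1), 3, 1)
  set.seed(1)
  out <- resample_offspring(thirds, 100L)
  expect_equal(sort(as.vector(out)), c(33L, 33L, 34L))
  # the extra egg lands on different cells across draws
  winners <- replicate(60, which.max(resample_offspring(thirds, 100L)))
  expect_equal(sort(unique(winners)), 1:3)
})

test_that("resampling preserves cell frequencies to within 1/n_pop", {
  set.seed(5)
  for (rep in 1:20) {
    offspring <- matrix(rpois(40, lambda = runif(1, 1, 50)), 8, 5)
    if (sum(offspring) == 0) offspring[1] <- 1
    n_pop <- sample(c(100L, 997L, 5000L), 1L)
    out <- resample_offspring(offspring, n_pop)
    expect_equal(sum(out), n_pop)
    err <- abs(out / n_pop - offspring / sum(offspring))
    expect_true(all(err <= 1 / n_pop + 1e-12))
  }
})

test_that("an extinct cohort raises a classed extinction error", {
  expect_error(resample_offspring(matrix(0, 2, 2), 100L),
               class = "extinctionError")
})

test_that("convergence means exactly one trait left standing", {
  traits <- trait_grid()
  counts <- matrix(0L, 80L, 51L)
  counts[37L, c(3L, 10L)] <- 5L
  cc <- check_convergence(counts, traits)
  expect_true(cc$converged)
  expect_equal(cc$dominant$exit_mean, traits$exit_mean[37L])
  counts[38L, 1L] <- 1L
  cc2 <- check_convergence(counts, traits)
  expect_false(cc2$converged)
  expect_equal(cc2$dominant_freq, 10 / 11)
  expect_error(check_convergence(matrix(0L, 2, 2), traits[1:2, ]), "empty")
})

test_that("every simulated individual receives exactly one fate", {
  ftab <- fixture_ftab()
  traits <- trait_grid()
  W <- copevolve:::exit_weight_matrix(traits, ftab$exit_grid)
  counts <- init_population(5 * 80 * length(ftab$spawn_bins),
                            n_bins = length(ftab$spawn_bins))
  set.seed(3)
  stp <- run_generation(counts, 1L, ftab, W)
  s <- stp$summary
  fate_sum <- s$pred1 + s$pred2 + s$pred3 + s$pred_diap + s$starved_dev +
    s$adults
  expect_equal(fate_sum, sum(counts))
  expect_equal(s$cohort_n, sum(counts))
  expect_gte(s$adults, 0)
  expect_true(all(stp$offspring >= 0))
})

test_that("with no mortality the offspring count is exactly adults times fecundity", {
  # synthetic world: every egg becomes an adult and lays 7 eggs into bin 3
  bins <- c(100L, 150L, 200L)
  ftab <- synthetic_ftab(function(y, bi, ei) sure_cell(3L, 7L, 3L),
                         spawn_bins = bins, exit_grid = c(110L))
  traits <- data.frame(exit_mean = 110, sdpv = 0)
  W <- matrix(1, 1, 1)
  counts <- matrix(c(10L, 20L, 30L), 1, 3)
  stp <- run_generation(counts, 1L, ftab, W)
  expect_equal(stp$summary$adults, 60)
  expect_equal(sum(stp$offspring), 60 * 7)
  expect_equal(as.vector(stp$offspring), c(0, 0, 420))
})

test_that("certain early predation yields zero offspring", {
  bins <- c(100L, 150L)
  dead_cell <- function(y, bi, ei) {
    cell <- sure_cell(1L, 5L, 2L)
    cell$probs <- c(1, 0, 0, 0, 0, 0, 0)  # predated in phase 1, always
    cell
  }
  ftab <- synthetic_ftab(dead_cell, spawn_bins = bins, exit_grid = c(110L))
  counts <- matrix(5L, 1, 2)
  stp <- run_generation(counts, 1L, ftab, matrix(1, 1, 1))
  expect_equal(sum(stp$offspring), 0)
  expect_equal(stp$summary$pred1, 10)
})

test_that("a trait with twofold offspring advantage sweeps to fixation", {
  # two traits, deterministic fecundities 8 vs 4: frequency ratio doubles
  # every generation until fixation
  bins <- c(100L, 150L)
  exits <- c(100L, 120L)
  cells <- function(y, bi, ei) sure_cell(bi, if (ei == 1L) 8L else 4L, 2L)
  ftab <- synthetic_ftab(cells, spawn_bins = bins, exit_grid = exits)
  traits <- data.frame(exit_mean = c(100, 120), sdpv = c(0, 0))
  W <- copevolve:::exit_weight_matrix(traits, exits)
  counts <- matrix(500L, 2, 2)
  set.seed(9)
  freqs <- numeric(14)
  for (g in 1:14) {
    stp <- run_generation(counts, 1L, ftab, W)
    counts <- resample_offspring(stp$offspring, 2000L)
    freqs[g] <- sum(counts[1L, ]) / 2000
  }
  expect_true(all(diff(freqs) >= 0))
  # proportional resampling keeps a ~1-egg remainder alive; near-fixation
  expect_gt(freqs[14], 0.998)
  # logistic growth of the frequency ratio: odds double each generation
  odds <- freqs / (1 - freqs)
  expect_equal(odds[2:4] / odds[1:3], rep(2, 3), tolerance = 0.1)
})

test_that("cell-wise fate sampling agrees with per-individual Bernoulli fates", {
  # the same trajectory, sampled 2000 times individually, must reproduce
  # the fate-cell category probabilities used by the engine
  f <- fixture_forcing()
  store <- fixture_store()
  mp <- mortality_params()
  ftab <- fixture_ftab()
  traj <- lookup_trajectory(store, 1, 130, 110)
  bi <- match(130L, ftab$spawn_bins); ei <- match(110L, ftab$exit_grid)
  cell <- ftab$tables[[1L]][[bi]][[ei]]
  expect_equal(sum(cell$probs), 1, tolerance = 1e-9)
  set.seed(77)
  n <- 2000L
  fates <- replicate(n, {
    ft <- sample_fate(traj, f, mp)
    if (ft$fate == "predated") {
      if (ft$phase <= 3) paste0("pred", ft$phase)
      else if (ft$phase <= 5) "pred_diap"
      else "adult"
    } else if (ft$fate == "starved" && !traj$reached_adult) "starved_dev"
    else "adult"
  })
  emp <- table(factor(fates, levels = c("pred1", "pred2", "pred3",
                                        "pred_diap", "starved_dev", "adult")))
  p_cat <- c(cell$probs[1:5], sum(cell$probs[-(1:5)]))
  keep <- p_cat * n >= 5
  chi <- suppressWarnings(chisq.test(emp[keep], p = p_cat[keep] / sum(p_cat[keep])))
  expect_gt(chi$p.value, 0.001)
})

test_that("neutral traits show no systematic winner", {
  # four traits with identical deterministic life histories but stochastic
  # survival: across replicates, mean final frequency stays at 1/4
  bins <- c(100L)
  coin_cell <- function(y, bi, ei) {
    cell <- sure_cell(1L, 6L, 1L)
    cell$probs <- c(0.5, 0, 0, 0, 0, 0, 0.5)
    cell
  }
  ftab <- synthetic_ftab(coin_cell, spawn_bins = bins, exit_grid = c(80L))
  traits <- data.frame(exit_mean = rep(80, 4), sdpv = c(0, 0, 0, 0))
  W <- matrix(1, 4, 1)
  set.seed(13)
  finals <- replicate(40, {
    counts <- matrix(50L, 4, 1)
    for (g in 1:15) {
      stp <- run_generation(counts, 1L, ftab, W)
      counts <- resample_offspring(stp$offspring, 200L)
    }
    counts[1L] / 200
  })
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.25), 4 * se + 0.02)
})

test_that("the evolutionary loop fixes the oracle-optimal trait", {
  # a decisive single-year scenario: strong selection fixes the trait the
  # deterministic expected-fitness oracle ranks first
  ftab <- fixture_ftab()
  oo <- expected_fitness_oracle(ftab)
  best <- oo[which.max(oo$growth_rate), ]
  n_cells <- 80L * length(ftab$spawn_bins)
  cfg <- run_config(n_pop_init = n_cells * 10L,
                    n_pop_reduced = n_cells * 5L,
                    max_generations = 200L, seed = 42L,
                    convergence_extra_years = 2L)
  res <- run_to_convergence(cfg, ftab)
  expect_s3_class(res, "evolution_result")
  expect_equal(res$trait$sdpv, best$sdpv)
  expect_lte(abs(res$trait$exit_mean - best$exit_mean), 10)
  expect_equal(nrow(res$analysis), 2L)
  # per-generation summaries conserve individuals
  g <- res$generations
  expect_true(all(g$pred1 + g$pred2 + g$pred3 + g$pred_diap +
                    g$starved_dev + g$adults == g$cohort_n))
})

test_that("identical config and seed reproduce the identical run", {
  ftab <- fixture_ftab()
  n_cells <- 80L * length(ftab$spawn_bins)
  cfg <- run_config(n_pop_init = n_cells * 4L, n_pop_reduced = n_cells * 2L,
                    max_generations = 60L, seed = 7L,
                    convergence_extra_years = 1L)
  r1 <- suppressWarnings(run_to_convergence(cfg, ftab))
  r2 <- suppressWarnings(run_to_convergence(cfg, ftab))
  expect_identical(r1$trait, r2$trait)
  expect_identical(r1$generations, r2$generations)
  expect_identical(r1$records$fates, r2$records$fates)
})

test_that("expected offspring per egg reduces to fecundity without mortality", {
  bins <- c(100L, 150L)
  exits <- c(100L, 120L)
  cells <- function(y, bi, ei) sure_cell(bi, if (ei == 1L) 8L else 4L, 2L)
  ftab <- synthetic_ftab(cells, spawn_bins = bins, exit_grid = exits)
  # point mass on exit 100 -> 8 eggs; on 120 -> 4; an even mixture -> 6
  expect_equal(expected_offspring_per_egg(100, 0, 100L, ftab), 8)
  expect_equal(expected_offspring_per_egg(120, 0, 150L, ftab), 4)
  w <- exit_day_weights(110, 10, exits)
  expect_equal(expected_offspring_per_egg(110, 10, 100L, ftab),
               sum(w * c(8, 4)))
})

test_that("constant per-day survival gives the closed-form adult probability", {
  # flat world: every day in development carries the same hazard
  f <- flat_forcing(food_total = 6, sst = 9)
  tr <- simulate_trajectory(1, 130, 110, f)
  mp <- mortality_params()
  cell <- copevolve:::fate_cell(tr, f, mp, spawn_bins = spawn_bin_grid())
  adult_first <- match(6L, tr$phase)
  p_by_day <- vapply(seq_len(adult_first - 1L), function(i)
    predation_prob(9, tr$phase[i], mp), numeric(1L))
  expect_equal(cell$p_adult, prod(1 - p_by_day), tolerance = 1e-12)
})
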