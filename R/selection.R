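# Selection engine: multi-generation loop over a cohort of eggs laid out on
# the (trait x spawn bin) grid. Individuals sharing a trait, spawn bin and
# realized exit day are exchangeable, so the engine samples whole cells at a
# time: a multinomial over realized exit days, then a multinomial over the
# exact death-day distribution of the cell's trajectory. This is
# distributionally identical to per-individual daily Bernoulli draws.

# fate-table category layout: 1-4 predation by phase group, 5 starvation (or
# any other death) before adulthood, then L adult death days, then survival.
FATE_PRED1 <- 1L; FATE_PRED2 <- 2L; FATE_PRED3 <- 3L
FATE_PRED_DIAP <- 4L; FATE_STARVED_DEV <- 5L

bin_index <- function(doy, spawn_bins = spawn_bin_grid()) {
  b <- 5 * floor(doy / 5 + 0.5)
  i <- match(b, spawn_bins)
  i[is.na(i) | b < 50 | b > 300] <- 0L  # non-viable: outside the growing season
  as.integer(i)
}

exit_index <- function(exit_doy) (as.integer(exit_doy) - 50L) %/% 10L + 1L

#' Precompute stochastic fate tables for every stored trajectory
#'
#' For each (year, spawn bin, exit day) trajectory this computes the exact
#' distribution of an individual's fate under daily Bernoulli predation:
#' probabilities of death by predation in each phase group, of death before
#' adulthood by starvation, of reaching adulthood, and - conditional on
#' adulthood - the death-day distribution across the adult (phase 6) days,
#' together with the daily egg schedule binned to 5-day spawn bins.
#'
#' @param store A \code{trajectory_store}.
#' @param forcing The matching \code{forcing_series}.
#' @param mp A \code{mortality_params}.
#' @return An object of class \code{fate_tables}: nested list indexed by
#'   year, spawn-bin index, exit index.
#' @export
build_fate_tables <- function(store, forcing, mp = mortality_params()) {
  n_bins <- length(store$spawn_bins)
  n_exits <- length(store$exit_grid)
  ft <- lapply(store$years, function(y) {
    per_bin <- vector("list", n_bins)
    for (bi in seq_len(n_bins)) {
      per_exit <- vector("list", n_exits)
      for (ei in seq_len(n_exits)) {
        traj <- lookup_trajectory(store, y, store$spawn_bins[bi],
                                  store$exit_grid[ei])
        per_exit[[ei]] <- fate_cell(traj, forcing, mp, store$spawn_bins)
      }
      per_bin[[bi]] <- per_exit
    }
    per_bin
  })
  out <- list(years = store$years, spawn_bins = store$spawn_bins,
              exit_grid = store$exit_grid, tables = ft, mp = mp)
  class(out) <- "fate_tables"
  out
}

fate_cell <- function(traj, forcing, mp, spawn_bins = spawn_bin_grid()) {
  p <- trajectory_predation_probs(traj, forcing, mp)
  n <- length(p)
  adult_first <- if (traj$reached_adult) match(6L, traj$phase) else NA_integer_
  pre_idx <- if (is.na(adult_first)) seq_len(n) else seq_len(adult_first - 1L)
  p_pre <- p[pre_idx]
  s_pre <- cumprod(1 - p_pre)
  death_pre <- c(1, s_pre[-length(s_pre)]) * p_pre
  ph_pre <- traj$phase[pre_idx]
  probs <- numeric(5L)
  probs[FATE_PRED1] <- sum(death_pre[ph_pre == 1L])
  probs[FATE_PRED2] <- sum(death_pre[ph_pre == 2L])
  probs[FATE_PRED3] <- sum(death_pre[ph_pre == 3L])
  probs[FATE_PRED_DIAP] <- sum(death_pre[ph_pre %in% c(4L, 5L)])
  p_escape <- if (length(p_pre)) s_pre[length(s_pre)] else 1

  if (is.na(adult_first)) {
    # dies (or stalls to the lifespan cap) without reaching adulthood
    probs[FATE_STARVED_DEV] <- p_escape
    cell <- list(probs = probs, has_adult = FALSE, L = 0L,
                 p_adult = 0, expected_bin = numeric(length(spawn_bins)))
  } else {
    probs[FATE_STARVED_DEV] <- 0
    adult_idx <- adult_first:n
    L <- length(adult_idx)
    p6 <- p[adult_idx]
    s6 <- cumprod(1 - p6)
    cond_death6 <- c(1, s6[-L]) * p6
    survive6 <- s6[L]
    eggs6 <- traj$eggs[adult_idx]
    doy6 <- ((traj$day[adult_idx] - 1L) %% DAYS_PER_YEAR) + 1L
    bin6 <- bin_index(doy6, spawn_bins)
    # expected viable eggs per spawn bin for one egg entering this cell
    ok <- bin6 > 0L & eggs6 > 0
    expected_bin <- numeric(length(spawn_bins))
    if (any(ok)) {
      contrib <- eggs6[ok] * s6[ok]
      agg <- rowsum(contrib, bin6[ok])
      expected_bin[as.integer(rownames(agg))] <- agg[, 1L]
    }
    expected_bin <- expected_bin * p_escape
    cell <- list(probs = c(probs, p_escape * cond_death6, p_escape * survive6),
                 has_adult = TRUE, L = L, p_adult = p_escape,
                 eggs6 = eggs6, bin6 = bin6, doy6 = doy6,
                 arrival_doy = doy6[1L],
                 adult_starves = !is.na(traj$starvation_day),
                 starve_doy = if (!is.na(traj$starvation_day))
                   ((traj$starvation_day - 1L) %% DAYS_PER_YEAR) + 1L
                 else NA_integer_,
                 expected_bin = expected_bin)
  }
  cell$spawn_doy <- traj$spawn_doy
  cell$exit_doy <- traj$exit_doy
  cell
}

#' Initialize a founding egg cohort
#'
#' Uniform allocation: each (trait, spawn bin) combination receives
#' \code{n_pop / (n_traits * n_bins)} eggs; with the full 80-trait, 51-bin
#' grid and n_pop = 408,000 that is 100 eggs per combination.
#'
#' @param n_pop Total founding eggs; must divide evenly over the grid.
#' @param traits Trait grid (default \code{\link{trait_grid}()}).
#' @param n_bins Number of spawn bins (default 51).
#' @return Integer matrix of counts, traits x bins.
#' @export
init_population <- function(n_pop, traits = trait_grid(), n_bins = 51L) {
  n_cells <- nrow(traits) * n_bins
  if (n_pop %% n_cells != 0L)
    stop("init_population: n_pop (", n_pop,
         ") not divisible by trait x bin cells (", n_cells, ")")
  matrix(as.integer(n_pop / n_cells), nrow = nrow(traits), ncol = n_bins)
}

exit_weight_matrix <- function(traits, exit_grid = exit_day_grid()) {
  t(vapply(seq_len(nrow(traits)),
           function(i) exit_day_weights(traits$exit_mean[i], traits$sdpv[i],
                                        exit_grid),
           numeric(length(exit_grid))))
}

#' Simulate one generation of the cohort
#'
#' For every occupied (trait, spawn bin) cell: realize exit days from the
#' trait's discretized Gaussian, sample each sub-cell's fate from the exact
#' death-day distribution of its trajectory, and credit surviving mothers'
#' daily eggs (inheriting the maternal trait) to the nearest 5-day spawn bin
#' of the following calendar year. Eggs falling outside bins 50-300 are
#' discarded as non-viable.
#'
#' @param counts Integer matrix traits x bins of eggs entering the
#'   generation.
#' @param year_index Base-year index of the cohort's spawn days.
#' @param ftab A \code{fate_tables}.
#' @param W Exit-weight matrix from \code{exit_weight_matrix} (rows matching
#'   \code{counts}).
#' @param record If TRUE, keep per-cell fate and phenology records for the
#'   analysis pass.
#' @return List with \code{offspring} (counts matrix for the next
#'   generation), \code{summary} (one-row data frame) and optionally
#'   \code{records}.
#' @export
run_generation <- function(counts, year_index, ftab, W, record = FALSE) {
  n_traits <- nrow(counts); n_bins <- ncol(counts)
  n_exits <- length(ftab$exit_grid)
  offspring <- matrix(0, n_traits, n_bins)
  fate_tot <- numeric(5L); adults_tot <- 0; eggs_tot <- 0; discarded_tot <- 0
  yt <- ftab$tables[[match(year_index, ftab$years)]]
  rec <- if (record) new.env(parent = emptyenv()) else NULL
  if (record) {
    rec$fates <- list(); rec$deaths <- list(); rec$arrivals <- list()
    rec$eggs <- list(); rec$i <- 0L
  }

  active <- which(counts > 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(active))) {
    ti <- active[r, 1L]; bi <- active[r, 2L]
    n <- counts[ti, bi]
    ex_n <- if (n_exits > 1L)
      stats::rmultinom(1L, n, W[ti, ])[, 1L]
    else n
    for (ei in which(ex_n > 0L)) {
      m <- ex_n[ei]
      cell <- yt[[bi]][[ei]]
      draw <- stats::rmultinom(1L, m, cell$probs)[, 1L]
      fate_tot <- fate_tot + draw[1:5]
      adults <- if (cell$has_adult) sum(draw[-(1:5)]) else 0L
      adults_tot <- adults_tot + adults
      n_pred6 <- 0L; n_starv6 <- 0L; n_surv6 <- 0L
      if (adults > 0L) {
        deaths6 <- draw[5L + seq_len(cell$L)]
        alive <- adults - cumsum(deaths6)
        live_eggs <- cell$eggs6 * alive
        ok <- cell$bin6 > 0L & live_eggs > 0
        if (any(ok)) {
          agg <- rowsum(live_eggs[ok], cell$bin6[ok])
          offspring[ti, as.integer(rownames(agg))] <-
            offspring[ti, as.integer(rownames(agg))] + agg[, 1L]
          eggs_tot <- eggs_tot + sum(agg)
        }
        discarded_tot <- discarded_tot + sum(live_eggs[cell$bin6 == 0L])
        n_pred6 <- sum(deaths6)
        n_end <- draw[length(draw)]
        if (cell$adult_starves) n_starv6 <- n_end else n_surv6 <- n_end
      }
      if (record) {
        rec$i <- rec$i + 1L
        i <- rec$i
        rec$fates[[i]] <- c(bin = ftab$spawn_bins[bi],
                            exit_doy = ftab$exit_grid[ei],
                            pred1 = draw[1L], pred2 = draw[2L],
                            pred3 = draw[3L], pred_diap = draw[4L],
                            starved_dev = draw[5L], adult = adults)
        if (adults > 0L) {
          rec$arrivals[[i]] <- c(exit_doy = ftab$exit_grid[ei],
                                 doy = cell$arrival_doy, count = adults)
          dd <- which(deaths6 > 0L)
          if (length(dd) || n_starv6 > 0L) {
            rec$deaths[[i]] <- data.frame(
              doy = c(cell$doy6[dd],
                      if (n_starv6 > 0L) cell$starve_doy),
              cause = c(rep("predation", length(dd)),
                        if (n_starv6 > 0L) "starvation"),
              count = c(deaths6[dd], if (n_starv6 > 0L) n_starv6))
          }
          ge <- which(live_eggs > 0)
          if (length(ge))
            rec$eggs[[i]] <- data.frame(doy = cell$doy6[ge],
                                        bin = 5L * floor(cell$doy6[ge] / 5 + 0.5),
                                        count = live_eggs[ge])
        }
      }
    }
  }

  cohort_n <- sum(counts)
  summary <- data.frame(
    year = year_index,
    cohort_n = cohort_n,
    pred1 = fate_tot[1L], pred2 = fate_tot[2L], pred3 = fate_tot[3L],
    pred_diap = fate_tot[4L], starved_dev = fate_tot[5L],
    adults = adults_tot,
    eggs = eggs_tot,
    eggs_discarded = discarded_tot,
    fecundity = if (adults_tot > 0) eggs_tot / adults_tot else NA_real_,
    survivorship = adults_tot / cohort_n)
  out <- list(offspring = offspring, summary = summary)
  if (record) {
    not_empty <- function(lst) length(lst) > 0L &&
      !all(vapply(lst, is.null, logical(1L)))
    out$records <- list(
      fates = as.data.frame(do.call(rbind, rec$fates)),
      arrivals = if (not_empty(rec$arrivals))
        as.data.frame(do.call(rbind, rec$arrivals)) else
          data.frame(exit_doy = integer(), doy = integer(), count = integer()),
      deaths = if (not_empty(rec$deaths))
        do.call(rbind, rec$deaths) else
          data.frame(doy = integer(), cause = character(), count = numeric()),
      eggs = if (not_empty(rec$eggs))
        do.call(rbind, rec$eggs) else
          data.frame(doy = integer(), bin = integer(), count = numeric()))
  }
  out
}

#' Frequency-preserving resampling to a fixed sub-population size
#'
#' Exactly \code{n_pop} eggs are carried into the next generation with cell
#' frequencies matching the offspring distribution as closely as integer
#' counts allow: largest-remainder proportional allocation, with random
#' tie-breaking among equal remainders (the only use of randomness).
#'
#' @param offspring Numeric matrix of offspring counts per cell.
#' @param n_pop Target total.
#' @return Integer matrix of the same shape summing to \code{n_pop}.
#' @export
resample_offspring <- function(offspring, n_pop) {
  tot <- sum(offspring)
  if (tot <= 0)
    stop(errorCondition("resample_offspring: cohort extinct (zero offspring)",
                        class = c("extinctionError", "error", "condition")))
  quota <- as.vector(offspring) * n_pop / tot
  base <- floor(quota)
  extra <- as.integer(round(n_pop - sum(base)))
  out <- base
  if (extra > 0L) {
    rem <- quota - base
    ord <- order(-rem, sample.int(length(rem)))
    out[ord[seq_len(extra)]] <- out[ord[seq_len(extra)]] + 1
  }
  matrix(as.integer(out), nrow(offspring), ncol(offspring))
}

#' Convergence check
#'
#' The population has converged when every remaining egg carries the same
#' trait pair (strict fixation).
#'
#' @param counts Counts matrix traits x bins.
#' @param traits Matching trait grid.
#' @return List with \code{converged} flag and \code{dominant} trait row
#'   (the trait with the highest total count).
#' @export
check_convergence <- function(counts, traits) {
  tot <- rowSums(counts)
  if (sum(tot) == 0) stop("check_convergence: empty cohort")
  dom <- which.max(tot)
  list(converged = sum(tot > 0) == 1L,
       dominant = traits[dom, , drop = FALSE],
       dominant_freq = tot[dom] / sum(tot))
}

#' Run configuration for an evolutionary simulation
#'
#' @param n_pop_init Founding cohort size (full scale 408,000 = 100 eggs per
#'   trait x bin cell; the desk preset uses 8,160 = 2 per cell).
#' @param n_pop_reduced Sub-population size after the initial generations
#'   (full scale 100,000).
#' @param reduce_after_generation Generation after which the reduced size
#'   applies (default 20).
#' @param max_generations Stop (reporting non-convergence) after this many
#'   generations.
#' @param convergence_extra_years Generations of the post-convergence
#'   analysis pass with full records (a full pass of the forcing sequence).
#' @param seed Integer RNG seed.
#' @param forced_sdpv Optional fixed SDPV restricting the trait grid.
#' @param start_year Base-year index of the founding cohort's spawn days.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(n_pop_init = 408000L, n_pop_reduced = 100000L,
                       reduce_after_generation = 20L, max_generations = 400L,
                       convergence_extra_years = 10L, seed = 1L,
                       forced_sdpv = NULL, start_year = 1L) {
  cfg <- list(n_pop_init = as.integer(n_pop_init),
              n_pop_reduced = as.integer(n_pop_reduced),
              reduce_after_generation = as.integer(reduce_after_generation),
              max_generations = as.integer(max_generations),
              convergence_extra_years = as.integer(convergence_extra_years),
              seed = as.integer(seed),
              forced_sdpv = forced_sdpv,
              start_year = as.integer(start_year))
  class(cfg) <- "run_config"
  cfg
}

#' Desk-scale run configuration
#'
#' A scaled-down configuration (2 eggs per trait x bin cell, 8,160 founding
#' eggs, reduced size 4,080, at most 200 generations) that lets a full
#' evolutionary run finish in seconds to minutes while keeping at least one
#' individual per cell at initialization.
#'
#' @param ... Overrides passed to \code{\link{run_config}}.
#' @return A \code{run_config}.
#' @export
desk_config <- function(...) {
  defaults <- list(n_pop_init = 8160L, n_pop_reduced = 4080L,
                   max_generations = 200L)
  args <- utils::modifyList(defaults, list(...))
  do.call(run_config, args)
}

#' Run the evolutionary simulation to trait fixation
#'
#' Loops generation simulation and frequency-preserving resampling under the
#' sub-population size schedule until a single trait pair remains (or
#' \code{max_generations} is hit, which is reported, not silent). After
#' convergence an analysis pass of \code{convergence_extra_years}
#' generations is simulated with full records - one complete pass of the
#' forcing sequence - for the phenology diagnostics.
#'
#' @param cfg A \code{run_config}.
#' @param ftab A \code{fate_tables} (from \code{\link{build_fate_tables}}).
#' @param quiet Suppress per-generation progress messages.
#' @return An object of class \code{evolution_result}: converged flag,
#'   dominant/converged trait, per-generation summary table and the
#'   analysis-pass records.
#' @export
run_to_convergence <- function(cfg, ftab, quiet = TRUE) {
  set.seed(cfg$seed)
  traits <- trait_grid(cfg$forced_sdpv)
  W <- exit_weight_matrix(traits, ftab$exit_grid)
  n_bins <- length(ftab$spawn_bins)
  n_years <- length(ftab$years)
  counts <- init_population(cfg$n_pop_init, traits, n_bins)
  year <- cfg$start_year
  summaries <- vector("list", cfg$max_generations)
  converged <- FALSE
  gen <- 0L
  while (gen < cfg$max_generations) {
    gen <- gen + 1L
    step <- run_generation(counts, year, ftab, W)
    n_pop <- if (gen <= cfg$reduce_after_generation) cfg$n_pop_init
             else cfg$n_pop_reduced
    counts <- resample_offspring(step$offspring, n_pop)
    year <- (year %% n_years) + 1L
    cc <- check_convergence(counts, traits)
    s <- cbind(generation = gen, step$summary,
               n_traits = sum(rowSums(counts) > 0),
               dominant_exit = cc$dominant$exit_mean,
               dominant_sdpv = cc$dominant$sdpv,
               dominant_freq = cc$dominant_freq)
    summaries[[gen]] <- s
    if (!quiet)
      message(sprintf(
        "generation %d (year %d): %d traits, dominant (%d, %d) at %.3f",
        gen, s$year, s$n_traits, s$dominant_exit, s$dominant_sdpv,
        cc$dominant_freq))
    if (cc$converged) { converged <- TRUE; break }
  }
  cc <- check_convergence(counts, traits)
  if (!converged)
    warning("run_to_convergence: no fixation after ", gen,
            " generations; dominant trait (",
            cc$dominant$exit_mean, ", ", cc$dominant$sdpv, ") at frequency ",
            signif(cc$dominant_freq, 3))

  # analysis pass: a full pass of the forcing sequence with detailed records
  rec_gens <- vector("list", cfg$convergence_extra_years)
  analysis <- vector("list", cfg$convergence_extra_years)
  for (k in seq_len(cfg$convergence_extra_years)) {
    step <- run_generation(counts, year, ftab, W, record = TRUE)
    tag <- function(df) {
      if (nrow(df) == 0L) {
        df$generation <- integer(); df$spawn_year <- integer()
        df$exit_year <- integer()
      } else {
        df$generation <- gen + k
        df$spawn_year <- year
        df$exit_year <- (year %% n_years) + 1L
      }
      df
    }
    rec_gens[[k]] <- lapply(step$records, tag)
    analysis[[k]] <- cbind(generation = gen + k, step$summary)
    counts <- resample_offspring(step$offspring, cfg$n_pop_reduced)
    year <- (year %% n_years) + 1L
  }
  records <- list(
    fates = do.call(rbind, lapply(rec_gens, `[[`, "fates")),
    arrivals = do.call(rbind, lapply(rec_gens, `[[`, "arrivals")),
    deaths = do.call(rbind, lapply(rec_gens, `[[`, "deaths")),
    eggs = do.call(rbind, lapply(rec_gens, `[[`, "eggs")))
  class(records) <- "evolution_records"

  res <- list(converged = converged,
              trait = cc$dominant,
              dominant_freq = cc$dominant_freq,
              n_generations = gen,
              generations = do.call(rbind, summaries[seq_len(gen)]),
              analysis = do.call(rbind, analysis),
              records = records,
              config = cfg,
              n_years = n_years)
  class(res) <- "evolution_result"
  res
}

#' @export
print.evolution_result <- function(x, ...) {
  cat(sprintf(
    "<evolution_result> %s after %d generations: trait (exit %d, SDPV %d)%s\n",
    if (x$converged) "converged" else "NOT converged", x$n_generations,
    x$trait$exit_mean, x$trait$sdpv,
    if (x$converged) "" else sprintf(" at frequency %.3f", x$dominant_freq)))
  invisible(x)
}

#' Expected lifetime reproductive output per egg
#'
#' Deterministic expectation for one egg of a given trait in a given spawn
#' bin and year: over the realized-exit probability mass, the probability of
#' surviving predation to adulthood times the expected number of viable eggs
#' produced (each day's eggs weighted by the probability of surviving
#' predation to that day). No sampling involved.
#'
#' @param exit_mean,sdpv Trait pair.
#' @param bin Spawn bin (day of year).
#' @param ftab A \code{fate_tables}.
#' @param year Base-year index of the spawn day.
#' @return Expected viable eggs per egg (scalar).
#' @export
expected_offspring_per_egg <- function(exit_mean, sdpv, bin, ftab, year = 1L) {
  w <- exit_day_weights(exit_mean, sdpv, ftab$exit_grid)
  bi <- match(bin, ftab$spawn_bins)
  yt <- ftab$tables[[match(year, ftab$years)]]
  sum(vapply(seq_along(ftab$exit_grid), function(ei)
    w[ei] * sum(yt[[bi]][[ei]]$expected_bin), numeric(1L)))
}

trait_projection_matrix <- function(exit_mean, sdpv, ftab, year = 1L) {
  w <- exit_day_weights(exit_mean, sdpv, ftab$exit_grid)
  yt <- ftab$tables[[match(year, ftab$years)]]
  n_bins <- length(ftab$spawn_bins)
  M <- matrix(0, n_bins, n_bins)
  for (bi in seq_len(n_bins)) {
    col <- numeric(n_bins)
    for (ei in which(w > 1e-12)) {
      col <- col + w[ei] * yt[[bi]][[ei]]$expected_bin[seq_len(n_bins)]
    }
    M[, bi] <- col
  }
  M
}

#' Deterministic expected-fitness oracle
#'
#' Independent prediction of the trait that selection should fix: the
#' asymptotic per-generation growth rate of a lineage carrying the trait.
#' Each year contributes a spawn-bin projection matrix (expected viable eggs
#' in bin b' next year per egg in bin b this year, from the exact survival
#' and fecundity expectations - no sampling); the growth rate is the
#' dominant eigenvalue of that matrix for repeat-year forcing, and the
#' per-cycle geometric growth of the year-sequence matrix product for
#' interannual forcing. Under frequency-preserving resampling, trait
#' frequencies evolve as renormalized independent branching processes, so
#' the trait with the largest growth rate is the predicted fixation winner.
#'
#' @param ftab A \code{fate_tables}.
#' @param traits Trait grid to evaluate (default the full 80).
#' @param n_cycles Power-iteration passes through the year sequence.
#' @return The trait grid with a \code{growth_rate} column (per-generation
#'   multiplication factor), sorted as given.
#' @export
expected_fitness_oracle <- function(ftab, traits = trait_grid(),
                                    n_cycles = 60L) {
  n_years <- length(ftab$years)
  gr <- vapply(seq_len(nrow(traits)), function(i) {
    Ms <- lapply(ftab$years, function(y)
      trait_projection_matrix(traits$exit_mean[i], traits$sdpv[i], ftab, y))
    v <- rep(1, length(ftab$spawn_bins))
    log_growth <- 0
    for (cyc in seq_len(n_cycles)) {
      log_cycle <- 0
      for (M in Ms) {
        v <- M %*% v
        s <- sum(v)
        if (s == 0) return(0)
        log_cycle <- log_cycle + log(s)
        v <- v / s
      }
      log_growth <- log_cycle
    }
    exp(log_growth / n_years)
  }, numeric(1L))
  out <- traits
  out$growth_rate <- gr
  out
}
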