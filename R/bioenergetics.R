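#' Bioenergetic parameters
#'
#' Parameters of the carbon-only daily bioenergetic core. The life cycle has
#' six phases: 1 non-feeding egg/early nauplius (temperature-dependent timer),
#' 2 feeding growth of structure, 3 growth plus lipid accumulation up to the
#' diapause-entry thresholds, 4 diapause at depth with ~100-fold suppressed
#' metabolism fuelled by lipid, 5 a fixed-length gonad-maturation period at
#' depth (also lipid-fuelled, plus a provisioning cost), and 6 income-breeding
#' adult at the surface converting net carbon gain to eggs.
#'
#' Ingestion and basal metabolism are biomass-specific rates on structural
#' carbon, both with a Q10 of 2; ingestion follows a multiple-resource
#' Holling type III (sigmoidal) response to summed food concentration.
#' Diapause entry requires structural biomass of 6.5 umol C together with a
#' lipid store of 7.52 umol C (80 percent of 9.4), i.e. total biomass
#' ~14.0 umol C.
#'
#' @param phase1_days_at_10C Phase-1 duration at 10 degrees C (days).
#' @param dev_q10 Q10 of phase-1 development rate.
#' @param graz_imax_ref Maximum specific ingestion rate at \code{t_ref_bio}
#'   (d^-1 on structural C).
#' @param graz_half_sat Half-saturation food concentration (mmol C m^-3).
#' @param graz_q10 Q10 of maximum ingestion rate.
#' @param assimilation_efficiency Fraction of ingested C assimilated.
#' @param basal_metab_ref Specific basal metabolic rate at \code{t_ref_bio}
#'   (d^-1 on structural C).
#' @param metab_q10 Q10 of basal metabolism.
#' @param t_ref_bio Reference temperature for ingestion/metabolism (deg C).
#' @param diapause_metab_factor Metabolic suppression factor in diapause.
#' @param structure_at_diapause Structural C required for diapause entry
#'   (umol C).
#' @param lipid_at_diapause Lipid C required for diapause entry (umol C).
#' @param phase2to3_structure Structural C at which lipid deposition begins
#'   (umol C).
#' @param phase5_days Duration of the gonad-maturation phase (days).
#' @param gonad_lipid_frac Fraction of \code{lipid_at_diapause} consumed as a
#'   gonad-provisioning cost, spread evenly over phase 5.
#' @param egg_carbon Carbon content of one egg (umol C); also the initial
#'   structural biomass of a newly spawned egg.
#' @param starve_structure_frac An individual dies of starvation once
#'   structural C is catabolized below this fraction of its maximum attained
#'   structure (after lipid is exhausted).
#' @param deep_t Default deep-water temperature when no forcing is attached
#'   (deg C).
#' @param max_lifespan_days Hard cap on the simulated lifespan (days).
#' @return An object of class \code{bio_params}.
#' @export
bio_params <- function(phase1_days_at_10C = 7,
                       dev_q10 = 2,
                       graz_imax_ref = 0.3,
                       graz_half_sat = 1.5,
                       graz_q10 = 2,
                       assimilation_efficiency = 0.7,
                       basal_metab_ref = 0.03,
                       metab_q10 = 2,
                       t_ref_bio = 9,
                       diapause_metab_factor = 0.01,
                       structure_at_diapause = 6.5,
                       lipid_at_diapause = 0.80 * 9.4,
                       phase2to3_structure = 3,
                       phase5_days = 14,
                       gonad_lipid_frac = 0.25,
                       egg_carbon = 0.023,
                       starve_structure_frac = 0.7,
                       deep_t = 4,
                       max_lifespan_days = 730) {
  p <- list(phase1_days_at_10C = phase1_days_at_10C,
            dev_q10 = dev_q10,
            graz_imax_ref = graz_imax_ref,
            graz_half_sat = graz_half_sat,
            graz_q10 = graz_q10,
            assimilation_efficiency = assimilation_efficiency,
            basal_metab_ref = basal_metab_ref,
            metab_q10 = metab_q10,
            t_ref_bio = t_ref_bio,
            diapause_metab_factor = diapause_metab_factor,
            structure_at_diapause = structure_at_diapause,
            lipid_at_diapause = lipid_at_diapause,
            phase2to3_structure = phase2to3_structure,
            phase5_days = phase5_days,
            gonad_lipid_frac = gonad_lipid_frac,
            egg_carbon = egg_carbon,
            starve_structure_frac = starve_structure_frac,
            deep_t = deep_t,
            max_lifespan_days = as.integer(max_lifespan_days))
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v > 0, logical(1L))))
  if (p$diapause_metab_factor >= 0.5)
    stop("diapause_metab_factor must be a strong suppression (<< 1)")
  class(p) <- "bio_params"
  p
}

#' Duration of the non-feeding phase 1
#'
#' Temperature-dependent development time of the egg through early nauplius
#' stages: the reference duration at 10 degrees C scaled by the development
#' Q10, rounded up to whole days (daily time step).
#'
#' @param T_c Temperature (degrees C).
#' @param p A \code{bio_params}.
#' @return Duration in whole days.
#' @export
phase1_duration <- function(T_c, p = bio_params()) {
  stopifnot(is.finite(T_c))
  ceiling(p$phase1_days_at_10C * p$dev_q10^((10 - T_c) / 10))
}

q10_scale <- function(T_c, t_ref, q10) q10^((T_c - t_ref) / 10)

holling3 <- function(S, k) S^2 / (k^2 + S^2)

#' Ingestion rate
#'
#' Multiple-resource Holling type III functional response on summed food
#' concentration, with a temperature-dependent (Q10 = 2) maximum specific
#' rate. Feeding occurs only in phases 2, 3 and 6; other phases ingest zero.
#'
#' @param food Numeric vector of food concentrations (mmol C m^-3); summed
#'   over components.
#' @param T_c Surface temperature (degrees C).
#' @param p A \code{bio_params}.
#' @param structure_c Structural biomass the specific rate acts on (umol C;
#'   default 1 gives the specific rate itself).
#' @param phase Life-cycle phase (1-6); non-feeding phases return 0.
#' @return Ingestion rate (umol C d^-1).
#' @export
grazing_rate <- function(food, T_c, p = bio_params(), structure_c = 1,
                         phase = 2L) {
  if (any(food < 0)) stop("grazing_rate: negative food concentration")
  if (phase %in% c(1L, 4L, 5L)) return(0)
  S <- sum(food)
  imax <- p$graz_imax_ref * q10_scale(T_c, p$t_ref_bio, p$graz_q10)
  imax * holling3(S, p$graz_half_sat) * structure_c
}

#' Initial state of a newly spawned individual
#'
#' @param p A \code{bio_params}.
#' @param T_c Surface temperature on the spawn day (sets the phase-1 timer).
#' @return A state list for \code{\link{step_individual}}.
#' @export
initial_state <- function(p = bio_params(), T_c = 10) {
  list(phase = 1L,
       structure_c = p$egg_carbon,
       lipid_c = 0,
       timer = phase1_duration(T_c, p),
       egg_pool = 0,
       max_structure = p$egg_carbon,
       alive = TRUE,
       starved = FALSE,
       eggs_today = 0L)
}

# Pay a carbon deficit from lipid first, then structural catabolism; sets
# starved when structure falls below the tolerated fraction of its maximum.
pay_deficit <- function(state, deficit, p) {
  from_lipid <- min(state$lipid_c, deficit)
  state$lipid_c <- state$lipid_c - from_lipid
  deficit <- deficit - from_lipid
  if (deficit > 0) {
    state$structure_c <- state$structure_c - deficit
    if (state$structure_c < p$starve_structure_frac * state$max_structure) {
      state$alive <- FALSE
      state$starved <- TRUE
    }
  }
  state
}

#' Advance an individual by one day
#'
#' One daily update of the bioenergetic state. Phase transitions driven by
#' internal state (timer expiry 1 to 2, structural threshold 2 to 3, both
#' diapause-entry thresholds 3 to 4) happen here; calendar-driven transitions
#' (4 to 5 at the committed exit day minus the phase-5 duration, 5 to 6 on
#' the exit day itself) are imposed by the caller via \code{enter_phase}.
#'
#' @param state State list as from \code{\link{initial_state}}.
#' @param env List with \code{food} (vector or summed concentration,
#'   mmol C m^-3), \code{sst} (deg C) and optionally \code{deep_t} (deg C).
#' @param p A \code{bio_params}.
#' @param enter_phase Optional integer: force entry into phase 5 or 6 at the
#'   start of this day.
#' @return Updated state; \code{eggs_today} holds eggs spawned this day.
#' @export
step_individual <- function(state, env, p = bio_params(), enter_phase = NULL) {
  stopifnot(state$phase %in% 1:6)
  if (!state$alive) return(state)
  if (!is.null(enter_phase)) state$phase <- as.integer(enter_phase)
  state$eggs_today <- 0L
  deep_t <- if (is.null(env$deep_t)) p$deep_t else env$deep_t
  S <- sum(env$food)
  if (S < 0) stop("step_individual: negative food concentration")
  phase <- state$phase

  if (phase == 1L) {
    state$timer <- state$timer - 1L
    if (state$timer <= 0L) state$phase <- 2L
    return(state)
  }

  if (phase %in% c(2L, 3L, 6L)) {
    Tf <- q10_scale(env$sst, p$t_ref_bio, p$metab_q10)
    assim <- p$assimilation_efficiency *
      grazing_rate(S, env$sst, p, state$structure_c, phase)
    metab <- p$basal_metab_ref * Tf * state$structure_c
    net <- assim - metab
    if (net >= 0) {
      if (phase == 2L) {
        state$structure_c <- state$structure_c + net
        if (state$structure_c >= p$phase2to3_structure) state$phase <- 3L
      } else if (phase == 3L) {
        to_structure <- min(net, max(0, p$structure_at_diapause - state$structure_c))
        state$structure_c <- state$structure_c + to_structure
        state$lipid_c <- state$lipid_c + (net - to_structure)
        if (state$structure_c >= p$structure_at_diapause &&
            state$lipid_c >= p$lipid_at_diapause)
          state$phase <- 4L
      } else {
        state$egg_pool <- state$egg_pool + net
        eggs <- floor(state$egg_pool / p$egg_carbon)
        state$egg_pool <- state$egg_pool - eggs * p$egg_carbon
        state$eggs_today <- as.integer(eggs)
      }
    } else {
      state <- pay_deficit(state, -net, p)
    }
    state$max_structure <- max(state$max_structure, state$structure_c)
    return(state)
  }

  # deep-water phases: lipid-fuelled metabolism at constant deep temperature
  Tf <- q10_scale(deep_t, p$t_ref_bio, p$metab_q10)
  metab <- p$basal_metab_ref * Tf * state$structure_c
  if (phase == 4L) {
    state <- pay_deficit(state, p$diapause_metab_factor * metab, p)
  } else {
    gonad_daily <- p$gonad_lipid_frac * p$lipid_at_diapause / p$phase5_days
    state <- pay_deficit(state, metab + gonad_daily, p)
  }
  state
}

#' Simulate one deterministic life-history trajectory
#'
#' Runs the daily bioenergetic core for one (spawn year, spawn day, exit day)
#' combination under the given forcing. The individual is committed to exit
#' diapause (arrive at the surface as an adult, phase 6) on day-of-year
#' \code{exit_doy} of the calendar year after its spawn year; gonad
#' maturation (phase 5) starts \code{phase5_days} before that. If the
#' individual has not entered diapause by then the trajectory is non-viable
#' (zero fitness), not an error. Purely deterministic: identical inputs give
#' identical trajectories; predation is applied elsewhere.
#'
#' @param spawn_year Base-year index of the spawn day (1-based).
#' @param spawn_doy Spawn day of year.
#' @param exit_doy Diapause-exit day of year (in year \code{spawn_year + 1}).
#' @param forcing A \code{forcing_series} covering the spawn day plus the
#'   maximum lifespan.
#' @param p A \code{bio_params}.
#' @return An object of class \code{copepod_trajectory}: per-day records of
#'   phase, structural C, lipid C, eggs spawned and deep-water residence,
#'   plus the starvation day (if any) and viability/adult flags.
#' @export
simulate_trajectory <- function(spawn_year, spawn_doy, exit_doy, forcing,
                                p = bio_params()) {
  spawn_abs <- (spawn_year - 1L) * DAYS_PER_YEAR + as.integer(spawn_doy)
  exit_abs <- spawn_year * DAYS_PER_YEAR + as.integer(exit_doy)
  n_max <- p$max_lifespan_days
  if (spawn_abs + n_max - 1L > length(forcing$sst))
    stop("simulate_trajectory: forcing does not cover the trajectory span")
  days <- spawn_abs:(spawn_abs + n_max - 1L)
  S_all <- total_food(forcing)[days]
  sst_all <- forcing$sst[days]
  deep_t <- forcing$deep_temperature

  phase <- integer(n_max); structure <- numeric(n_max)
  lipid <- numeric(n_max); eggs <- integer(n_max)
  state <- initial_state(p, sst_all[1L])
  starvation_day <- NA_integer_
  viable <- TRUE
  reached_adult <- FALSE
  phase5_start <- exit_abs - p$phase5_days
  n_rec <- 0L

  for (i in seq_len(n_max)) {
    d_abs <- days[i]
    enter <- NULL
    if (d_abs == phase5_start) {
      if (state$phase == 4L) {
        enter <- 5L
      } else {
        viable <- FALSE   # never reached diapause in time: zero fitness
        break
      }
    } else if (d_abs == exit_abs && state$phase == 5L) {
      enter <- 6L
      reached_adult <- TRUE
    }
    state <- step_individual(state,
                             list(food = S_all[i], sst = sst_all[i],
                                  deep_t = deep_t),
                             p, enter_phase = enter)
    n_rec <- i
    phase[i] <- state$phase
    structure[i] <- state$structure_c
    lipid[i] <- state$lipid_c
    eggs[i] <- state$eggs_today
    if (!state$alive) {
      starvation_day <- d_abs
      break
    }
  }

  idx <- seq_len(n_rec)
  traj <- list(spawn_year = as.integer(spawn_year),
               spawn_doy = as.integer(spawn_doy),
               exit_doy = as.integer(exit_doy),
               spawn_day = spawn_abs,
               exit_day = exit_abs,
               day = days[idx],
               phase = phase[idx],
               structure_c = structure[idx],
               lipid_c = lipid[idx],
               eggs = eggs[idx],
               deep = phase[idx] %in% c(4L, 5L),
               starvation_day = starvation_day,
               viable = viable && n_rec > 0L,
               reached_adult = reached_adult)
  class(traj) <- "copepod_trajectory"
  traj
}

#' @export
print.copepod_trajectory <- function(x, ...) {
  cat(sprintf(
    "<copepod_trajectory> year %d spawn doy %d exit doy %d: %d days, %s, %d eggs\n",
    x$spawn_year, x$spawn_doy, x$exit_doy, length(x$day),
    if (!x$viable) "non-viable"
    else if (x$reached_adult) "reached adult"
    else "died in development",
    sum(x$eggs)))
  invisible(x)
}

#' Default spawn-bin and exit-day grids
#'
#' Egg spawn dates are binned to 51 five-day bins across the growing season
#' (days 50 to 300); diapause exit sits on a 16-value ten-day grid (days 50
#' to 200).
#'
#' @name grids
#' @export
spawn_bin_grid <- function() seq(50L, 300L, by = 5L)

#' @rdname grids
#' @export
exit_day_grid <- function() seq(50L, 200L, by = 10L)

traj_key <- function(year, bin, exit) sprintf("y%d_b%d_e%d", year, bin, exit)

#' Precompute the trajectory lookup store
#'
#' Runs \code{\link{simulate_trajectory}} for every combination of spawn
#' year, spawn bin and exit day, so that the multi-generation population
#' model can follow individuals by table lookup instead of re-integrating
#' the bioenergetics.
#'
#' @param forcing A \code{forcing_series}.
#' @param spawn_bins Spawn-day grid (default \code{\link{spawn_bin_grid}}).
#' @param exit_grid Exit-day grid (default \code{\link{exit_day_grid}}).
#' @param p A \code{bio_params}.
#' @param years Base-year indices to build (default all distinct years).
#' @param progress Emit a progress line per year to stderr.
#' @return An object of class \code{trajectory_store}.
#' @export
build_lookup <- function(forcing, spawn_bins = spawn_bin_grid(),
                         exit_grid = exit_day_grid(), p = bio_params(),
                         years = seq_len(forcing$n_years), progress = FALSE) {
  if (length(spawn_bins) == 0L || length(exit_grid) == 0L)
    stop("build_lookup: empty grid")
  env <- new.env(parent = emptyenv())
  for (y in years) {
    for (b in spawn_bins) {
      for (e in exit_grid) {
        env[[traj_key(y, b, e)]] <- simulate_trajectory(y, b, e, forcing, p)
      }
    }
    if (progress)
      message(sprintf("build_lookup: year %d done (%d trajectories)",
                      y, length(spawn_bins) * length(exit_grid)))
  }
  store <- list(trajectories = env,
                years = as.integer(years),
                spawn_bins = as.integer(spawn_bins),
                exit_grid = as.integer(exit_grid),
                params = p)
  class(store) <- "trajectory_store"
  store
}

#' @export
print.trajectory_store <- function(x, ...) {
  cat(sprintf("<trajectory_store> %d years x %d spawn bins x %d exit days = %d trajectories\n",
              length(x$years), length(x$spawn_bins), length(x$exit_grid),
              length(ls(x$trajectories))))
  invisible(x)
}

#' Retrieve a stored trajectory
#'
#' @param store A \code{trajectory_store}.
#' @param year,spawn_doy,exit_doy Exact key of the trajectory.
#' @return The stored \code{copepod_trajectory}.
#' @export
lookup_trajectory <- function(store, year, spawn_doy, exit_doy) {
  key <- traj_key(year, spawn_doy, exit_doy)
  traj <- store$trajectories[[key]]
  if (is.null(traj))
    stop("lookup_trajectory: no stored trajectory for key ", key)
  traj
}

#' Persist a trajectory store as a single indexed CSV
#'
#' Columns \code{year,spawn_bin,exit_day,day,phase,structure_c,lipid_c,eggs,deep};
#' the reload round-trip is bit-exact.
#'
#' @param store A \code{trajectory_store}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_store <- function(store, path) {
  pieces <- lapply(ls(store$trajectories), function(k) {
    tr <- store$trajectories[[k]]
    data.table::data.table(year = tr$spawn_year, spawn_bin = tr$spawn_doy,
                           exit_day = tr$exit_doy, day = tr$day,
                           phase = tr$phase,
                           # 17 significant digits: doubles survive the
                           # text round-trip bit-exactly
                           structure_c = sprintf("%.17g", tr$structure_c),
                           lipid_c = sprintf("%.17g", tr$lipid_c),
                           eggs = tr$eggs,
                           deep = as.integer(tr$deep))
  })
  tab <- data.table::rbindlist(pieces)
  data.table::setorder(tab, year, spawn_bin, exit_day, day)
  data.table::fwrite(tab, path)
  invisible(path)
}

#' Reload a trajectory store written by \code{\link{write_trajectory_store}}
#'
#' Starvation/viability/adult flags are reconstructed from the records:
#' they are pure functions of the stored daily series.
#'
#' @param path CSV path.
#' @param p The \code{bio_params} the store was built with.
#' @return A \code{trajectory_store}.
#' @export
read_trajectory_store <- function(path, p = bio_params()) {
  tab <- data.table::fread(path)
  env <- new.env(parent = emptyenv())
  keys <- unique(tab[, c("year", "spawn_bin", "exit_day")])
  split_tab <- split(tab, by = c("year", "spawn_bin", "exit_day"))
  for (piece in split_tab) {
    y <- piece$year[1L]; b <- piece$spawn_bin[1L]; e <- piece$exit_day[1L]
    n <- nrow(piece)
    spawn_abs <- (y - 1L) * DAYS_PER_YEAR + b
    exit_abs <- y * DAYS_PER_YEAR + e
    last_phase <- piece$phase[n]
    # a record that stops short of the lifespan cap ended either in
    # starvation or at the failed phase-5 commitment check
    truncated <- n < p$max_lifespan_days
    failed_commit <- truncated && last_phase < 4L &&
      piece$day[n] == exit_abs - p$phase5_days - 1L
    traj <- list(spawn_year = y, spawn_doy = b, exit_doy = e,
                 spawn_day = spawn_abs, exit_day = exit_abs,
                 day = piece$day, phase = piece$phase,
                 structure_c = as.numeric(piece$structure_c),
                 lipid_c = as.numeric(piece$lipid_c),
                 eggs = piece$eggs, deep = piece$deep == 1L,
                 starvation_day = if (truncated && !failed_commit)
                   piece$day[n] else NA_integer_,
                 viable = !failed_commit && n > 0L,
                 reached_adult = any(piece$phase == 6L))
    class(traj) <- "copepod_trajectory"
    env[[traj_key(y, b, e)]] <- traj
  }
  store <- list(trajectories = env,
                years = sort(unique(keys$year)),
                spawn_bins = sort(unique(keys$spawn_bin)),
                exit_grid = sort(unique(keys$exit_day)),
                params = p)
  class(store) <- "trajectory_store"
  store
}
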