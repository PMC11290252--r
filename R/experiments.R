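# Experiment drivers reproducing the study designs at configurable scale:
# repeat-year (RY) and interannual (IA) scenarios, mortality sensitivities,
# replicate ensembles. The cmd_* functions are what the copevolve command
# line (inst/exec/copevolve) dispatches to.

#' Experiment specification
#'
#' @param name Experiment label used in output file names.
#' @param scenario List: \code{type} "RY" or "IA"; for RY, a
#'   \code{bloom_peak_day} and optional \code{anomalous} flag select the
#'   repeated year; IA uses the decade preset.
#' @param sensitivity One of "none", "flat_mortality", "scale1.5",
#'   "scale2.0", "sdpv_off".
#' @param replicates Number of replicate runs (>= 1).
#' @param seeds Integer seeds, one per replicate (default 1..replicates).
#' @param scale "desk" (default) or "full" population sizing.
#' @return An object of class \code{experiment_spec}.
#' @export
experiment_spec <- function(name = "experiment",
                            scenario = list(type = "RY", bloom_peak_day = 150),
                            sensitivity = c("none", "flat_mortality",
                                            "scale1.5", "scale2.0",
                                            "sdpv_off"),
                            replicates = 1L,
                            seeds = NULL,
                            scale = c("desk", "full")) {
  sensitivity <- match.arg(sensitivity)
  scale <- match.arg(scale)
  if (replicates < 1L) stop("experiment_spec: replicates must be >= 1")
  if (is.null(seeds)) seeds <- seq_len(replicates)
  if (length(seeds) != replicates)
    stop("experiment_spec: need one seed per replicate")
  if (!scenario$type %in% c("RY", "IA"))
    stop("experiment_spec: scenario type must be RY or IA")
  spec <- list(name = name, scenario = scenario, sensitivity = sensitivity,
               replicates = as.integer(replicates), seeds = as.integer(seeds),
               scale = scale)
  class(spec) <- "experiment_spec"
  spec
}

scenario_configs <- function(scenario) {
  if (scenario$type == "IA") {
    decade_preset()
  } else {
    list(repeat_year_preset(
      bloom_peak_day = if (is.null(scenario$bloom_peak_day)) 150
                       else scenario$bloom_peak_day,
      anomalous = isTRUE(scenario$anomalous)))
  }
}

scenario_mortality <- function(sensitivity) {
  switch(sensitivity,
         "flat_mortality" = mortality_preset("flat"),
         "scale1.5" = mortality_preset("x1.5"),
         "scale2.0" = mortality_preset("x2"),
         mortality_preset("default"))
}

#' Write a synthetic forcing scenario to CSV
#'
#' @param out Output CSV path.
#' @param scenario "decade" for the 10-year interannual preset, or "ry" for
#'   a single repeat-year.
#' @param bloom_peak_day Bloom peak for the "ry" scenario.
#' @param anomalous Apply the anomalous-year modifications ("ry" only).
#' @return The output path, invisibly.
#' @export
cmd_make_forcing <- function(out, scenario = c("decade", "ry"),
                             bloom_peak_day = 150, anomalous = FALSE) {
  scenario <- match.arg(scenario)
  cfgs <- if (scenario == "decade") decade_preset()
          else list(repeat_year_preset(bloom_peak_day, anomalous))
  series <- assemble_sequence(cfgs, n_passes = 1L, lookahead_days = 0L)
  write_forcing_table(series, out)
  invisible(out)
}

build_hash <- function(forcing_csv, p, spawn_bins, exit_grid) {
  sig <- paste(unname(tools::md5sum(forcing_csv)),
               paste(unlist(p), collapse = ","),
               paste(spawn_bins, collapse = ","),
               paste(exit_grid, collapse = ","), sep = "|")
  # a stable fingerprint of the inputs; md5 of the signature string
  tmp <- tempfile()
  writeLines(sig, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' Build (or reuse) the trajectory lookup store for a forcing file
#'
#' Simulates the full (year x spawn bin x exit day) grid and writes it as an
#' indexed CSV next to a hash of the inputs; a rebuild with unchanged inputs
#' is a no-op.
#'
#' @param forcing_csv Base-cycle forcing CSV (from
#'   \code{\link{cmd_make_forcing}}).
#' @param out Output store CSV path.
#' @param p A \code{bio_params}.
#' @param spawn_bins,exit_grid Grids (defaults the full 51 x 16).
#' @param progress Per-year progress lines to stderr.
#' @return The store (class \code{trajectory_store}), invisibly.
#' @export
cmd_build_trajectories <- function(forcing_csv, out, p = bio_params(),
                                   spawn_bins = spawn_bin_grid(),
                                   exit_grid = exit_day_grid(),
                                   progress = TRUE) {
  hash <- build_hash(forcing_csv, p, spawn_bins, exit_grid)
  hash_file <- paste0(out, ".hash")
  if (file.exists(out) && file.exists(hash_file) &&
      identical(readLines(hash_file, n = 1L), as.character(hash))) {
    message("cmd_build_trajectories: store up to date, skipping rebuild")
    return(invisible(read_trajectory_store(out, p)))
  }
  base <- read_forcing_table(forcing_csv)
  forcing <- extend_forcing(base)
  store <- build_lookup(forcing, spawn_bins, exit_grid, p,
                        progress = progress)
  write_trajectory_store(store, out)
  writeLines(as.character(hash), hash_file)
  invisible(store)
}

modal_trait <- function(traits_df) {
  key <- paste(traits_df$exit_mean, traits_df$sdpv)
  tab <- sort(table(key), decreasing = TRUE)
  parts <- as.integer(strsplit(names(tab)[1L], " ")[[1L]])
  data.frame(exit_mean = parts[1L], sdpv = parts[2L],
             support = as.integer(tab[1L]))
}

#' Run a replicate ensemble of evolutionary simulations
#'
#' Builds the scenario forcing, trajectory store and fate tables (unless
#' injected), runs one evolutionary simulation per replicate seed, and
#' reports the converged trait of each replicate plus the modal trait of
#' the ensemble. With \code{out_dir} set, per-replicate generation
#' summaries, analysis-pass records and a JSON manifest are written.
#'
#' @param spec An \code{experiment_spec}.
#' @param p A \code{bio_params}.
#' @param out_dir Optional output directory for the result bundle.
#' @param store,ftab Optional prebuilt \code{trajectory_store} /
#'   \code{fate_tables} to reuse across experiments.
#' @param quiet Suppress progress output.
#' @return List with \code{results} (one \code{evolution_result} per
#'   replicate), \code{traits} (data frame of converged traits) and
#'   \code{modal} (modal trait across the ensemble).
#' @export
cmd_evolve <- function(spec, p = bio_params(), out_dir = NULL, store = NULL,
                       ftab = NULL, quiet = TRUE) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (is.null(ftab)) {
    cfgs <- scenario_configs(spec$scenario)
    forcing <- assemble_sequence(cfgs)
    if (is.null(store)) {
      if (!quiet) message("cmd_evolve: building trajectory store...")
      store <- build_lookup(forcing, p = p, progress = !quiet)
    }
    ftab <- build_fate_tables(store, forcing,
                              scenario_mortality(spec$sensitivity))
  }
  # cohort sizes follow the active grid: 2 eggs/cell (desk) or 100 eggs/cell
  # (full) at initialization
  n_traits <- if (spec$sensitivity == "sdpv_off") 16L else 80L
  n_cells <- n_traits * length(ftab$spawn_bins)
  base_cfg <- if (spec$scale == "desk") {
    desk_config(n_pop_init = 2L * n_cells, n_pop_reduced = n_cells)
  } else {
    per_cell <- if (spec$sensitivity %in% c("scale1.5", "scale2.0"))
      500L else 100L   # high predation needs the larger founding cohort
    run_config(n_pop_init = per_cell * n_cells,
               n_pop_reduced = as.integer(25L * n_cells))
  }
  results <- vector("list", spec$replicates)
  for (i in seq_len(spec$replicates)) {
    cfg <- base_cfg
    cfg$seed <- spec$seeds[i]
    if (spec$sensitivity == "sdpv_off") cfg$forced_sdpv <- 0L
    if (!quiet) message(sprintf("cmd_evolve: replicate %d (seed %d)",
                                i, cfg$seed))
    results[[i]] <- tryCatch(
      run_to_convergence(cfg, ftab, quiet = quiet),
      extinctionError = function(e) {
        warning("replicate ", i, " (seed ", cfg$seed, ") went extinct")
        NULL
      })
  }
  alive <- !vapply(results, is.null, logical(1L))
  if (!any(alive)) stop("cmd_evolve: every replicate went extinct")
  traits <- do.call(rbind, lapply(results[alive], function(r)
    cbind(r$trait, converged = r$converged,
          n_generations = r$n_generations)))
  out <- list(results = results, traits = traits, modal = modal_trait(traits))
  if (!is.null(out_dir)) write_run_bundle(out, spec, out_dir)
  out
}

write_run_bundle <- function(ensemble, spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ensemble$results)) {
    r <- ensemble$results[[i]]
    if (is.null(r)) next
    pre <- file.path(out_dir, sprintf("%s_rep%02d", spec$name, i))
    utils::write.csv(r$generations, paste0(pre, "_generations.csv"),
                     row.names = FALSE)
    for (nm in names(r$records))
      utils::write.csv(r$records[[nm]], paste0(pre, "_", nm, ".csv"),
                       row.names = FALSE)
  }
  utils::write.csv(ensemble$traits,
                   file.path(out_dir, paste0(spec$name, "_traits.csv")),
                   row.names = FALSE)
  manifest <- list(name = spec$name, scenario = spec$scenario,
                   sensitivity = spec$sensitivity, scale = spec$scale,
                   seeds = spec$seeds,
                   modal_trait = as.list(ensemble$modal))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(spec$name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

read_run_bundle <- function(out_dir, name, replicate = 1L) {
  pre <- file.path(out_dir, sprintf("%s_rep%02d", name, replicate))
  files <- paste0(pre, "_", c("fates", "arrivals", "deaths", "eggs"), ".csv")
  if (!all(file.exists(files)))
    stop("read_run_bundle: bundle at ", out_dir,
         " has no analysis-pass records for '", name, "' replicate ",
         replicate)
  records <- lapply(files, utils::read.csv)
  names(records) <- c("fates", "arrivals", "deaths", "eggs")
  class(records) <- "evolution_records"
  records
}

#' Compute phenology diagnostics for a finished run
#'
#' Applies the post-convergence diagnostics (egg-fate decomposition by spawn
#' bin, per-year fecundity, survivorship, starvation fraction, daily adult
#' series) to an \code{evolution_result} or to a bundle directory written by
#' \code{\link{cmd_evolve}}, and optionally writes them as CSVs.
#'
#' @param x An \code{evolution_result}, \code{evolution_records}, or a
#'   bundle directory path.
#' @param out_dir Optional directory for the metric CSVs.
#' @param name,replicate Bundle selection when \code{x} is a directory.
#' @return List of data frames: \code{fate_by_bin}, \code{by_year},
#'   \code{adults_daily}.
#' @export
cmd_analyze <- function(x, out_dir = NULL, name = "experiment",
                        replicate = 1L) {
  records <- if (is.character(x)) read_run_bundle(x, name, replicate)
             else as_records(x)
  years <- sort(unique(records$fates$exit_year))
  fate_by_bin <- egg_fate_decomposition(records)
  by_year <- do.call(rbind, lapply(years, function(y) data.frame(
    year = y,
    fecundity = fecundity_per_female(records, y),
    survivorship = survivorship(records, y),
    starvation_fraction = starvation_fraction(records, y))))
  adults_daily <- do.call(rbind, lapply(years, function(y)
    cbind(year = y, adult_timeseries(records, y))))
  out <- list(fate_by_bin = fate_by_bin, by_year = by_year,
              adults_daily = adults_daily)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fate_by_bin, file.path(out_dir, "fate_by_bin.csv"),
                     row.names = FALSE)
    utils::write.csv(by_year, file.path(out_dir, "metrics_by_year.csv"),
                     row.names = FALSE)
    utils::write.csv(adults_daily, file.path(out_dir, "adults_daily.csv"),
                     row.names = FALSE)
  }
  out
}

#' Read an experiment specification from a YAML config file
#'
#' Keys mirror \code{\link{experiment_spec}}: \code{name},
#' \code{scenario} (with \code{type} and optional \code{bloom_peak_day},
#' \code{anomalous}), \code{sensitivity}, \code{replicates}, \code{seeds},
#' \code{scale}.
#'
#' @param path YAML file path.
#' @return An \code{experiment_spec}.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(experiment_spec, cfg)
}
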