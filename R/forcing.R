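#' Annual forcing configuration
#'
#' Describes one synthetic year of seasonal environmental forcing: a spring
#' bloom in total food concentration superimposed on a winter baseline, split
#' into four fixed fractions (diatoms, non-diatoms, microzooplankton,
#' detritus), plus a sinusoidal sea-surface temperature cycle. The functional
#' forms emulate the structure of a high-latitude open-ocean station (a single
#' dominant spring food pulse, SST lagging the light season) without any
#' attempt to model mixed-layer physics.
#'
#' @param bloom_onset_day Day of year at which total food starts to rise above
#'   the winter baseline (start of the bloom window).
#' @param bloom_peak_day Day of year of maximum total food.
#' @param peak_food Total food at the bloom peak (mmol C m^-3).
#' @param baseline_food Total food outside the bloom window (mmol C m^-3).
#' @param food_fractions Numeric length-4 vector of proportions
#'   (diatom, nondiatom, microzoo, detritus); must sum to 1.
#' @param sst_min,sst_max Annual SST minimum and maximum (degrees C).
#' @param sst_peak_day Day of year at which SST peaks.
#' @param bloom_falloff_ratio Ratio of the post-peak to pre-peak width of the
#'   bloom pulse; values above 1 give the slow autumn decline of food typical
#'   of subarctic stations (default 4/3).
#' @return An object of class \code{annual_forcing_config}.
#' @export
annual_forcing_config <- function(bloom_onset_day = 60,
                                  bloom_peak_day = 150,
                                  peak_food = 6,
                                  baseline_food = 0.1,
                                  food_fractions = c(diatom = 0.45,
                                                     nondiatom = 0.3,
                                                     microzoo = 0.15,
                                                     detritus = 0.1),
                                  sst_min = 3.2,
                                  sst_max = 10.7,
                                  sst_peak_day = 215,
                                  bloom_falloff_ratio = 4 / 3) {
  cfg <- list(bloom_onset_day = bloom_onset_day,
              bloom_peak_day = bloom_peak_day,
              peak_food = peak_food,
              baseline_food = baseline_food,
              food_fractions = food_fractions,
              sst_min = sst_min,
              sst_max = sst_max,
              sst_peak_day = sst_peak_day,
              bloom_falloff_ratio = bloom_falloff_ratio)
  class(cfg) <- "annual_forcing_config"
  validate_forcing_config(cfg)
  cfg
}

validate_forcing_config <- function(cfg) {
  if (!is.numeric(cfg$baseline_food) || cfg$baseline_food < 0)
    stop("invalid forcing config: baseline_food must be >= 0")
  if (cfg$peak_food < cfg$baseline_food)
    stop("invalid forcing config: peak_food must be >= baseline_food")
  if (cfg$bloom_onset_day >= cfg$bloom_peak_day)
    stop("invalid forcing config: bloom_onset_day must precede bloom_peak_day")
  if (length(cfg$food_fractions) != 4L || any(cfg$food_fractions < 0))
    stop("invalid forcing config: food_fractions must be 4 non-negative proportions")
  if (abs(sum(cfg$food_fractions) - 1) > 1e-9)
    stop("invalid forcing config: food_fractions must sum to 1")
  if (cfg$sst_min > cfg$sst_max)
    stop("invalid forcing config: sst_min exceeds sst_max")
  if (is.null(cfg$bloom_falloff_ratio) || cfg$bloom_falloff_ratio <= 0)
    stop("invalid forcing config: bloom_falloff_ratio must be positive")
  invisible(cfg)
}

FOOD_COMPONENTS <- c("diatom", "nondiatom", "microzoo", "detritus")
DAYS_PER_YEAR <- 365L

new_forcing_series <- function(food, sst, deep_temperature = 4,
                               n_years = 1L) {
  stopifnot(nrow(food) == length(sst))
  colnames(food) <- FOOD_COMPONENTS
  x <- list(day = seq_len(nrow(food)),
            food = food,
            sst = sst,
            deep_temperature = deep_temperature,
            n_years = as.integer(n_years))
  class(x) <- "forcing_series"
  x
}

#' @export
print.forcing_series <- function(x, ...) {
  cat(sprintf(
    "<forcing_series> %d days (%d base year%s), deep T = %g degC\n",
    length(x$sst), x$n_years, if (x$n_years > 1) "s" else "",
    x$deep_temperature))
  invisible(x)
}

#' Total food concentration per day
#'
#' @param series A \code{forcing_series}.
#' @return Numeric vector of summed food concentration (mmol C m^-3).
#' @export
total_food <- function(series) rowSums(series$food)

#' Generate one synthetic year of forcing
#'
#' Total food is the winter baseline plus a truncated, asymmetric Gaussian
#' bloom pulse: the pulse rises from exactly the baseline at
#' \code{bloom_onset_day} (3 pre-peak standard deviations before the peak) to
#' exactly \code{peak_food} at \code{bloom_peak_day}, then decays with a
#' post-peak width \code{bloom_falloff_ratio} times the pre-peak width,
#' meeting the baseline again 3 post-peak standard deviations later. SST is a
#' sinusoid between \code{sst_min} and \code{sst_max} peaking at
#' \code{sst_peak_day}.
#'
#' @param cfg An \code{annual_forcing_config}.
#' @param deep_temperature Constant deep-water temperature (degrees C).
#' @return A \code{forcing_series} of 365 days.
#' @export
generate_annual_cycle <- function(cfg, deep_temperature = 4) {
  validate_forcing_config(cfg)
  d <- seq_len(DAYS_PER_YEAR)
  sigma_rise <- (cfg$bloom_peak_day - cfg$bloom_onset_day) / 3
  sigma_fall <- sigma_rise * cfg$bloom_falloff_ratio
  z <- (d - cfg$bloom_peak_day) /
    ifelse(d <= cfg$bloom_peak_day, sigma_rise, sigma_fall)
  # subtract the 3-sigma tail so the pulse meets the baseline exactly
  tail3 <- exp(-4.5)
  pulse <- pmax(0, (exp(-z^2 / 2) - tail3) / (1 - tail3))
  total <- cfg$baseline_food + (cfg$peak_food - cfg$baseline_food) * pulse
  food <- outer(total, cfg$food_fractions)
  sst_mean <- (cfg$sst_min + cfg$sst_max) / 2
  sst_amp <- (cfg$sst_max - cfg$sst_min) / 2
  sst <- sst_mean + sst_amp * cos(2 * pi * (d - cfg$sst_peak_day) / DAYS_PER_YEAR)
  new_forcing_series(food, sst, deep_temperature, n_years = 1L)
}

#' Concatenate annual cycles into a multi-year forcing series
#'
#' Years are laid end-on-end and the whole sequence is repeated
#' \code{n_passes} times, followed by a two-year cyclic lookahead so that a
#' trajectory spawned late in the final year can keep reading forcing (it
#' wraps around to the first year, emulating a sequence repeated
#' indefinitely).
#'
#' @param years List of \code{annual_forcing_config} (or a single config).
#' @param n_passes Number of times the year sequence is repeated.
#' @param deep_temperature Constant deep-water temperature (degrees C).
#' @param lookahead_days Extra cyclically-extended days appended (default two
#'   years, the maximum lifespan).
#' @return A \code{forcing_series}; \code{n_years} is the length of the base
#'   (distinct-year) cycle.
#' @export
assemble_sequence <- function(years, n_passes = 1L, deep_temperature = 4,
                              lookahead_days = 730L) {
  if (inherits(years, "annual_forcing_config")) years <- list(years)
  if (length(years) == 0L) stop("assemble_sequence: empty list of years")
  ann <- lapply(years, generate_annual_cycle, deep_temperature = deep_temperature)
  food1 <- do.call(rbind, lapply(ann, function(a) a$food))
  sst1 <- unlist(lapply(ann, function(a) a$sst), use.names = FALSE)
  base_len <- nrow(food1)
  n_total <- base_len * n_passes + lookahead_days
  idx <- ((seq_len(n_total) - 1L) %% base_len) + 1L
  new_forcing_series(food1[idx, , drop = FALSE], sst1[idx],
                     deep_temperature, n_years = length(years))
}

#' Read a forcing table from CSV
#'
#' Expects columns \code{day,diatom,nondiatom,microzoo,detritus,sst}. Records
#' at coarser-than-daily resolution (e.g. 5-day) are linearly interpolated to
#' daily; daily input is passed through unchanged.
#'
#' @param path CSV file path.
#' @param deep_temperature Constant deep-water temperature (degrees C).
#' @param n_years Number of distinct base years the file covers.
#' @return A \code{forcing_series}.
#' @export
read_forcing_table <- function(path, deep_temperature = 4, n_years = NULL) {
  tab <- utils::read.csv(path)
  need <- c("day", FOOD_COMPONENTS, "sst")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("forcing table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.unsorted(tab$day, strictly = TRUE))
    stop("forcing table: day column must be strictly increasing")
  bad <- which(apply(tab[FOOD_COMPONENTS], 1L, function(r) any(r < 0)))
  if (length(bad))
    stop("forcing table: negative food concentration at row ", bad[1L])
  days <- seq(min(tab$day), max(tab$day))
  food <- sapply(FOOD_COMPONENTS, function(cn)
    stats::approx(tab$day, tab[[cn]], xout = days)$y)
  sst <- stats::approx(tab$day, tab$sst, xout = days)$y
  if (is.null(n_years)) n_years <- max(1L, length(days) %/% DAYS_PER_YEAR)
  new_forcing_series(as.matrix(food), sst, deep_temperature, n_years)
}

#' Write a forcing series to CSV
#'
#' @param series A \code{forcing_series}.
#' @param path Output CSV path.
#' @param base_only Write only the base (distinct-year) cycle without the
#'   repeated passes and lookahead (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_forcing_table <- function(series, path, base_only = TRUE) {
  n <- if (base_only) series$n_years * DAYS_PER_YEAR else length(series$sst)
  tab <- data.frame(day = seq_len(n), series$food[seq_len(n), , drop = FALSE],
                    sst = series$sst[seq_len(n)])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cyclically extend a base forcing series
#'
#' Repeats the base (distinct-year) cycle of a series end-on-end and appends
#' a cyclic lookahead, exactly as \code{\link{assemble_sequence}} does for
#' configs; used after loading a base cycle from CSV.
#'
#' @param series A \code{forcing_series} holding exactly its base cycle.
#' @param n_passes Number of passes of the base cycle.
#' @param lookahead_days Extra cyclically-extended days appended.
#' @return A \code{forcing_series}.
#' @export
extend_forcing <- function(series, n_passes = 1L, lookahead_days = 730L) {
  base_len <- series$n_years * DAYS_PER_YEAR
  stopifnot(length(series$sst) >= base_len)
  n_total <- base_len * n_passes + lookahead_days
  idx <- ((seq_len(n_total) - 1L) %% base_len) + 1L
  new_forcing_series(series$food[idx, , drop = FALSE], series$sst[idx],
                     series$deep_temperature, n_years = series$n_years)
}

#' Day of early bloom onset
#'
#' First day of a given base year on which total food reaches a threshold
#' concentration; this is the phenological marker that optimal diapause exit
#' tracks under repeat-year forcing.
#'
#' @param series A \code{forcing_series}.
#' @param year_index Base-year index (1-based).
#' @param threshold Total food threshold (mmol C m^-3); default 2.
#' @return Day of year of first crossing, or \code{NA} if never reached.
#' @export
bloom_onset_day <- function(series, year_index = 1L, threshold = 2) {
  offset <- (year_index - 1L) * DAYS_PER_YEAR
  tot <- total_food(series)[offset + seq_len(DAYS_PER_YEAR)]
  hit <- which(tot >= threshold)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Decade forcing preset
#'
#' Ten synthetic years emulating the structure of an interannually variable
#' "present day" decade at a Norwegian Sea station: bloom peak days span day
#' 140 (earliest, year 4) to day 170 (latest, year 2). The early onset of
#' the bloom (first crossing of 2 mmol C m^-3) varies much more than the
#' peak - early-blooming years ramp up slowly from mid-winter while
#' late-blooming years rise steeply - so onsets span roughly days 95 to 143.
#' Year 2 is the anomalous year: the latest and steepest bloom combined with
#' a cold spring and a delayed SST peak; several other years are mildly
#' cool.
#'
#' @return A list of 10 \code{annual_forcing_config} objects.
#' @export
decade_preset <- function() {
  peak <- c(155, 170, 160, 140, 152, 158, 142, 150, 145, 156)
  onset <- c(83, 150, 100, 50, 77, 92, 52, 72, 61, 87)
  # post-peak width of the food pulse (days): early-bloom years have short
  # growing seasons, late-bloom years long ones; the anomalous year 2
  # combines the latest, steepest bloom with a long tail
  fall_sd <- c(38, 40, 38, 18, 30, 38, 18, 30, 18, 38)
  # cool-spring years get a slightly lower SST minimum; the anomalous year 2
  # is markedly colder in spring with a delayed SST peak
  sst_min <- c(2.7, 2.2, 2.7, 3.7, 3.2, 2.7, 3.7, 3.2, 3.7, 2.7)
  sst_peak <- c(215, 245, 218, 212, 215, 215, 212, 215, 212, 215)
  lapply(seq_len(10L), function(y)
    annual_forcing_config(bloom_onset_day = onset[y],
                          bloom_peak_day = peak[y],
                          sst_min = sst_min[y],
                          sst_peak_day = sst_peak[y],
                          bloom_falloff_ratio =
                            3 * fall_sd[y] / (peak[y] - onset[y])))
}

#' Single-year repeat-year preset
#'
#' @param bloom_peak_day Bloom peak day of year.
#' @param anomalous If TRUE, apply the anomalous-year modifications (cold
#'   spring SST, bloom delayed 30 days beyond \code{bloom_peak_day}).
#' @return An \code{annual_forcing_config}.
#' @export
repeat_year_preset <- function(bloom_peak_day = 150, anomalous = FALSE) {
  if (anomalous) {
    annual_forcing_config(bloom_onset_day = bloom_peak_day + 30 - 54,
                          bloom_peak_day = bloom_peak_day + 30,
                          sst_min = 2.2, sst_peak_day = 245,
                          bloom_falloff_ratio = 120 / 54)
  } else {
    annual_forcing_config(bloom_onset_day = bloom_peak_day - 90,
                          bloom_peak_day = bloom_peak_day)
  }
}
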