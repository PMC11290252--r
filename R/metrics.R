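# Post-convergence phenology diagnostics. All functions consume the
# analysis-pass records of an evolution run: four long tables (fates,
# arrivals, deaths, eggs) tagged with generation, spawn_year and exit_year.
# Egg-centric quantities (fate decomposition) are attributed to the spawn
# year; adult-centric quantities (fecundity, arrival/attrition series,
# starvation) to the calendar year of diapause exit.

as_records <- function(x) {
  if (inherits(x, "evolution_result")) x <- x$records
  if (!inherits(x, "evolution_records") &&
      !all(c("fates", "arrivals", "deaths", "eggs") %in% names(x)))
    stop("expected an evolution_result with an analysis pass, ",
         "or its records tables")
  if (is.null(x$fates) || nrow(x$fates) == 0L)
    stop("records contain no analysis pass (no simulated individuals)")
  x
}

FATE_CATEGORIES <- c("starved_dev", "pred1", "pred2", "pred3", "pred_diap",
                     "adult")

#' Decompose egg fates by spawn date
#'
#' Exhaustive, mutually exclusive categorization of every simulated egg by
#' its spawn bin: starvation during development (phases 1-3), predation in
#' phase 1 (eggs and non-feeding nauplii), phase 2 (growth), phase 3 (lipid
#' accumulation), predation at depth (diapause and gonad maturation), and
#' survival through to adulthood. Per-bin category counts sum exactly to the
#' eggs simulated in that bin.
#'
#' @param records An \code{evolution_result} or its records.
#' @param year Optional spawn year to restrict to (default: all).
#' @return Data frame with one row per spawn bin, category counts and the
#'   bin total.
#' @export
egg_fate_decomposition <- function(records, year = NULL) {
  r <- as_records(records)
  f <- r$fates
  if (!is.null(year)) f <- f[f$spawn_year == year, , drop = FALSE]
  if (nrow(f) == 0L)
    return(data.frame(bin = integer(), starved_dev = numeric(),
                      pred1 = numeric(), pred2 = numeric(), pred3 = numeric(),
                      pred_diap = numeric(), adult = numeric(),
                      total = numeric()))
  agg <- stats::aggregate(f[FATE_CATEGORIES], by = list(bin = f$bin), FUN = sum)
  agg$total <- rowSums(agg[FATE_CATEGORIES])
  agg[order(agg$bin), ]
}

#' Average fecundity per female
#'
#' Total eggs spawned by adults whose diapause exit falls in the given year,
#' divided by the number of adults arriving post-diapause that year.
#'
#' @param records An \code{evolution_result} or its records.
#' @param year Exit-year index.
#' @return Eggs per adult female; \code{NA} if no adults arrived.
#' @export
fecundity_per_female <- function(records, year) {
  r <- as_records(records)
  adults <- sum(r$arrivals$count[r$arrivals$exit_year == year])
  if (adults == 0) return(NA_real_)
  eggs <- sum(r$eggs$count[r$eggs$exit_year == year])
  eggs / adults
}

#' Egg-to-adult survivorship
#'
#' Adults arriving post-diapause in the given year divided by the eggs
#' simulated in the generation that produced them; always in [0, 1].
#'
#' @param records An \code{evolution_result} or its records.
#' @param year Exit-year index.
#' @return Adults per egg.
#' @export
survivorship <- function(records, year) {
  r <- as_records(records)
  f <- r$fates[r$fates$exit_year == year, , drop = FALSE]
  eggs <- sum(f[FATE_CATEGORIES])
  if (eggs == 0) return(0)
  sum(f$adult) / eggs
}

#' Daily post-diapause adult numbers
#'
#' Adults arrive in pulses on the 10-day exit grid and are then eroded daily
#' by predation and starvation, producing the characteristic saw-tooth
#' seasonal pattern. Counts are normalized to the total number of adults
#' arriving post-diapause in the year.
#'
#' @param records An \code{evolution_result} or its records.
#' @param year Exit-year index.
#' @return Data frame \code{doy}, \code{adults} (normalized), over days
#'   1-365.
#' @export
adult_timeseries <- function(records, year) {
  r <- as_records(records)
  arr <- r$arrivals[r$arrivals$exit_year == year, , drop = FALSE]
  total <- sum(arr$count)
  out <- data.frame(doy = seq_len(DAYS_PER_YEAR), adults = 0)
  if (total == 0) return(out)
  dth <- r$deaths[r$deaths$exit_year == year, , drop = FALSE]
  arrivals_by_day <- numeric(DAYS_PER_YEAR)
  a <- rowsum(arr$count, arr$doy)
  arrivals_by_day[as.integer(rownames(a))] <- a[, 1L]
  deaths_by_day <- numeric(DAYS_PER_YEAR)
  if (nrow(dth)) {
    d <- rowsum(dth$count, dth$doy)
    deaths_by_day[as.integer(rownames(d))] <- d[, 1L]
  }
  out$adults <- (cumsum(arrivals_by_day) - cumsum(deaths_by_day)) / total
  out
}

#' Fraction of post-diapause adults dying of starvation
#'
#' @param records An \code{evolution_result} or its records.
#' @param year Exit-year index.
#' @param day_window Length-2 day-of-year window (inclusive) in which
#'   starvation deaths are counted; default the whole year.
#' @return Starved adults in the window divided by adults arrived that year;
#'   \code{NA} if no adults arrived.
#' @export
starvation_fraction <- function(records, year, day_window = c(1, 365)) {
  r <- as_records(records)
  adults <- sum(r$arrivals$count[r$arrivals$exit_year == year])
  if (adults == 0) return(NA_real_)
  d <- r$deaths
  starved <- sum(d$count[d$exit_year == year & d$cause == "starvation" &
                           d$doy >= day_window[1L] & d$doy <= day_window[2L]])
  starved / adults
}
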