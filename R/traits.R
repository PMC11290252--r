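#' The heritable trait grid
#'
#' The heritable trait is the diapause-exit date, carried as a pair: a mean
#' exit day on a 16-value grid (Julian day 50 to 200, 10 days apart) and a
#' phenotypic-variance standard deviation SDPV in {0, 10, 20, 30, 40} days.
#' 16 x 5 = 80 combinations, returned in lexicographic order (mean, then
#' SDPV).
#'
#' @param forced_sdpv Optional single SDPV value to restrict the grid to
#'   (e.g. 0 for the no-variance sensitivity run).
#' @return Data frame with columns \code{exit_mean} and \code{sdpv}.
#' @export
trait_grid <- function(forced_sdpv = NULL) {
  sdpv <- c(0L, 10L, 20L, 30L, 40L)
  if (!is.null(forced_sdpv)) {
    if (!forced_sdpv %in% sdpv) stop("trait_grid: forced_sdpv not on the grid")
    sdpv <- as.integer(forced_sdpv)
  }
  g <- expand.grid(sdpv = sdpv, exit_mean = exit_day_grid())
  data.frame(exit_mean = g$exit_mean, sdpv = g$sdpv)
}

round10_half_away <- function(x) {
  sign(x) * 10 * floor(abs(x) / 10 + 0.5)
}

#' Realize the diapause-exit day of one individual
#'
#' An individual's realized exit day is its inherited mean plus a Gaussian
#' deviate with SD equal to the inherited SDPV, allocated to the nearest
#' 10-day setting of the trajectory grid (ties round half away from zero)
#' and clamped to the grid range [50, 200]. With SDPV = 0 the mean is
#' returned exactly. Drawn once per individual, at the egg stage.
#'
#' @param exit_mean Inherited mean exit day (multiple of 10 in [50, 200]).
#' @param sdpv Inherited phenotypic-variance SD (days).
#' @param n Number of independent draws.
#' @return Integer vector of realized exit days on the 10-day grid.
#' @export
realize_exit_day <- function(exit_mean, sdpv, n = 1L) {
  if (sdpv == 0) return(rep(as.integer(exit_mean), n))
  x <- exit_mean + round10_half_away(stats::rnorm(n, 0, sdpv))
  as.integer(pmin(200, pmax(50, x)))
}

#' Probability mass of realized exit days
#'
#' Exact discretized-Gaussian weights of \code{\link{realize_exit_day}} over
#' the exit grid: interior grid days receive the Gaussian mass of their
#' 10-day rounding cell and the two edge days absorb the clamped tails.
#'
#' @param exit_mean Mean exit day.
#' @param sdpv Phenotypic-variance SD (days); 0 gives a point mass.
#' @param grid Exit-day grid (default \code{\link{exit_day_grid}}).
#' @return Named numeric vector of probabilities summing to 1.
#' @export
exit_day_weights <- function(exit_mean, sdpv, grid = exit_day_grid()) {
  w <- numeric(length(grid))
  names(w) <- grid
  if (sdpv == 0) {
    w[as.character(exit_mean)] <- 1
    return(w)
  }
  lo <- stats::pnorm(grid - 5, exit_mean, sdpv)
  hi <- stats::pnorm(grid + 5, exit_mean, sdpv)
  w[] <- hi - lo
  w[1L] <- hi[1L]                       # all mass below 55 clamps to 50
  w[length(w)] <- 1 - lo[length(w)]     # all mass at/above 195 clamps to 200
  w
}

#' Inheritance of the trait pair
#'
#' Traits pass unchanged from mother to offspring: no mutation,
#' recombination or plasticity of the inherited values.
#'
#' @param trait List or one-row data frame with \code{exit_mean} and
#'   \code{sdpv}.
#' @return The identical trait.
#' @export
inherit <- function(trait) trait
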