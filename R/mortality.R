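#' Predation mortality parameters
#'
#' Stage-specific daily probabilities of death by predation. Pre-diapause
#' stages (phases 1-3) and post-diapause adults (phase 6) live in surface
#' waters where predation pressure tracks temperature through an exponential
#' relationship, m(T) = m(T_ref) * exp(b * (T - T_ref)) with b = 0.214
#' (equivalent to a Q10 of about 8.5); diapause and gonad maturation
#' (phases 4-5) take place in dark deep waters where the rate is an order of
#' magnitude lower and temperature-independent.
#'
#' @param m1_ref Daily probability for phases 1-3 at \code{t_ref} (d^-1).
#' @param m2 Daily probability for phases 4-5, never temperature-scaled
#'   (d^-1).
#' @param m3_ref Daily probability for phase 6 at \code{t_ref} (d^-1).
#' @param b Temperature coefficient of the exponential scaling (degC^-1).
#' @param t_ref Reference temperature (deg C), the growing-season mean SST.
#' @param scale Overall multiplier on all probabilities (sensitivity
#'   analyses use 1.5 and 2).
#' @param seasonal If TRUE (default) surface rates scale with temperature;
#'   if FALSE the reference rates apply year-round (flat-mortality
#'   sensitivity).
#' @return An object of class \code{mortality_params}.
#' @export
mortality_params <- function(m1_ref = 0.03, m2 = 0.002, m3_ref = 0.02,
                             b = 0.214, t_ref = 9, scale = 1,
                             seasonal = TRUE) {
  mp <- list(m1_ref = m1_ref, m2 = m2, m3_ref = m3_ref, b = b,
             t_ref = t_ref, scale = scale, seasonal = isTRUE(seasonal))
  if (any(c(m1_ref, m2, m3_ref) < 0) || any(c(m1_ref, m2, m3_ref) >= 1))
    stop("mortality_params: rates must lie in [0, 1)")
  if (b <= 0) stop("mortality_params: b must be positive")
  class(mp) <- "mortality_params"
  mp
}

#' Sensitivity presets for predation mortality
#'
#' \code{"default"} is the seasonal parameterization; \code{"flat"} removes
#' the temperature scaling of the surface rates; \code{"x1.5"} and
#' \code{"x2"} scale all probabilities by 1.5 and 2 while keeping the
#' seasonal trend.
#'
#' @param name One of \code{"default"}, \code{"flat"}, \code{"x1.5"},
#'   \code{"x2"}.
#' @return A \code{mortality_params}.
#' @export
mortality_preset <- function(name = c("default", "flat", "x1.5", "x2")) {
  name <- match.arg(name)
  switch(name,
         "default" = mortality_params(),
         "flat" = mortality_params(seasonal = FALSE),
         "x1.5" = mortality_params(scale = 1.5),
         "x2" = mortality_params(scale = 2))
}

#' Daily predation probability
#'
#' @param T_c Temperature (deg C); vectorized. Ignored for phases 4-5 and
#'   when \code{seasonal} is off.
#' @param phase Life-cycle phase (1-6).
#' @param mp A \code{mortality_params}.
#' @return Daily probability of death by predation, capped at 1.
#' @export
predation_prob <- function(T_c, phase, mp = mortality_params()) {
  if (!all(phase %in% 1:6)) stop("predation_prob: invalid phase")
  stopifnot(length(phase) == 1L)
  if (phase %in% 4:5) return(rep(min(1, mp$scale * mp$m2), length(T_c)))
  ref <- if (phase == 6L) mp$m3_ref else mp$m1_ref
  p <- if (mp$seasonal) {
    mp$scale * ref * exp(mp$b * (T_c - mp$t_ref))
  } else {
    rep(mp$scale * ref, length(T_c))
  }
  pmin(1, p)
}

#' Effective Q10 of the predation-temperature scaling
#'
#' @param mp A \code{mortality_params}.
#' @return \code{exp(10 * b)}, the factor by which surface predation
#'   probability rises per 10 degrees C.
#' @export
q10_factor <- function(mp = mortality_params()) exp(10 * mp$b)

#' Daily predation probabilities along a trajectory
#'
#' Surface days (phases 1-3 and 6) use the sea-surface temperature of the
#' forcing; deep days (phases 4-5) use the constant deep rate.
#'
#' @param traj A \code{copepod_trajectory}.
#' @param forcing The \code{forcing_series} the trajectory was built under.
#' @param mp A \code{mortality_params}.
#' @return Numeric vector of daily probabilities aligned with
#'   \code{traj$day}.
#' @export
trajectory_predation_probs <- function(traj, forcing, mp = mortality_params()) {
  sst <- forcing$sst[traj$day]
  p <- numeric(length(traj$day))
  for (ph in unique(traj$phase)) {
    i <- traj$phase == ph
    p[i] <- predation_prob(sst[i], ph, mp)
  }
  p
}

#' Sample the stochastic fate of one individual
#'
#' Draws one uniform random number per day of the trajectory; the individual
#' dies by predation on the first day the draw falls below that day's
#' probability. If it escapes predation, its fate is read off the
#' trajectory: starvation on the recorded starvation day, an adult survivor
#' if it reached phase 6 and the record ends with it alive, otherwise the
#' end of the simulated span.
#'
#' @param traj A \code{copepod_trajectory}.
#' @param forcing The matching \code{forcing_series}.
#' @param mp A \code{mortality_params}.
#' @return A list with \code{fate} (one of \code{"predated"},
#'   \code{"starved"}, \code{"adult_survivor"}, \code{"season_end"}),
#'   \code{day} (absolute day of the event or NA) and \code{phase}.
#' @export
sample_fate <- function(traj, forcing, mp = mortality_params()) {
  p <- trajectory_predation_probs(traj, forcing, mp)
  n <- length(p)
  u <- stats::runif(n)
  hit <- which(u < p)
  if (length(hit)) {
    i <- hit[1L]
    return(list(fate = "predated", day = traj$day[i], phase = traj$phase[i]))
  }
  if (!is.na(traj$starvation_day)) {
    i <- n
    return(list(fate = "starved", day = traj$starvation_day,
                phase = traj$phase[i]))
  }
  if (traj$reached_adult) {
    return(list(fate = "adult_survivor", day = NA_integer_, phase = 6L))
  }
  list(fate = "season_end", day = NA_integer_, phase = traj$phase[n])
}

#' Exact death-day distribution under daily Bernoulli predation
#'
#' Closed-form distribution of the day of death by predation for a given
#' daily-probability vector: P(die day i) = p_i * prod_{j<i}(1 - p_j), with
#' the residual mass on surviving every day. Sampling from this categorical
#' distribution is distributionally identical to the per-day Bernoulli
#' process; the selection engine uses it for whole cells at a time.
#'
#' @param p Vector of daily predation probabilities.
#' @return List with \code{death} (P(die on day i)) and \code{survive}
#'   (P(no predation over the whole span)).
#' @export
death_day_distribution <- function(p) {
  surv_before <- cumprod(c(1, 1 - p))[seq_along(p)]
  list(death = surv_before * p, survive = prod(1 - p))
}
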