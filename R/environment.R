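# Weather (Beaufort sea state and sightability) and daylight gating of visual
# and acoustic effort. A synthetic persistent Markov chain generates sea state
# when no observed record is supplied.

#' Generate a synthetic sea-state series
#'
#' First state drawn from the stationary weights; each subsequent step keeps
#' the current state with probability `transition_persistence`, else redraws
#' from the stationary weights (so the marginal distribution equals the
#' weights). Sightability is derived through `sightability_from_state`. With
#' the weather model disabled all steps have sea state 0 and the maximum
#' sightability.
#'
#' @param wp A [weather_params()] object.
#' @param n_steps Number of steps.
#' @return List of vectors `sea_state` and `sightability`, length `n_steps`.
#' @export
generate_weather <- function(wp, n_steps) {
  if (!wp$enabled) {
    return(list(sea_state = rep(0L, n_steps),
                sightability = rep(max(wp$sightability_from_state), n_steps)))
  }
  k <- length(wp$state_levels)
  idx <- integer(n_steps)
  idx[1] <- sample.int(k, 1, prob = wp$stationary_weights)
  if (n_steps > 1) {
    stay <- stats::runif(n_steps - 1) < wp$transition_persistence
    redraw <- sample.int(k, n_steps - 1, replace = TRUE,
                         prob = wp$stationary_weights)
    for (i in 2:n_steps) idx[i] <- if (stay[i - 1]) idx[i - 1] else redraw[i - 1]
  }
  list(sea_state = wp$state_levels[idx],
       sightability = wp$sightability_from_state[idx])
}

#' Is it daylight?
#'
#' Half-open daylight window: daylight iff `dawn <= time-of-day < dusk`.
#'
#' @param time Time since survey start, h.
#' @param dawn,dusk Hours of day.
#' @param start_hour Hour of day at survey start.
#' @return Logical (vectorised over `time`).
#' @export
is_daylight <- function(time, dawn = 6, dusk = 18, start_hour = 0) {
  tod <- (start_hour + time) %% 24
  tod >= dawn & tod < dusk
}

#' Which operations are allowed under current conditions?
#'
#' Acoustics operate whenever the sea state does not exceed the acoustic
#' maximum (and, if overnight acoustics are disabled, only in daylight).
#' Visual search requires daylight, sightability at or above the visual
#' minimum, and sea state at most Beaufort 5; above Beaufort 5 all operations
#' are suspended.
#'
#' @param sea_state Beaufort sea state.
#' @param sightability Sightability index.
#' @param daylight Logical.
#' @param ap An [acoustic_params()] object.
#' @param vp A [vessel_params()] object.
#' @param overnight_acoustics Logical.
#' @return List with logicals `visual_ok` and `acoustic_ok`.
#' @export
ops_allowed <- function(sea_state, sightability, daylight, ap, vp,
                        overnight_acoustics = TRUE) {
  acoustic_ok <- sea_state <= ap$max_sea_state &
    (overnight_acoustics | daylight)
  visual_ok <- daylight & sightability >= vp$min_sightability & sea_state <= 5
  list(visual_ok = visual_ok, acoustic_ok = acoustic_ok)
}
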