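# Listening stations (hydrophone dips and DIFAR sonobuoys): hard-disc
# detection, noisy bearings and aural distance estimates, the sonobuoy
# lifecycle, cross-bearing fixes and station/bearing scheduling.
# Bearings are degrees clockwise from north; the unit vector of bearing b is
# (sin b, cos b).

#' True bearing between two points
#'
#' @param from,to Length-2 numeric positions (km).
#' @return Bearing in degrees clockwise from north, in `[0, 360)`.
#' @export
true_bearing <- function(from, to) {
  dx <- to[1] - from[1]; dy <- to[2] - from[2]
  if (dx == 0 && dy == 0)
    stop("bearing undefined for coincident positions", call. = FALSE)
  (atan2(dx, dy) / DEG) %% 360
}

#' Detect vocalising groups within acoustic range of a station
#'
#' Hard-disc detection: exactly the groups that are currently vocalising and
#' lie within `effective_range` (closed disc) of the station are returned.
#' Detection within range is certain; the effective range plays the role of an
#' effective strip half-width.
#'
#' @param station_pos Length-2 numeric (km).
#' @param w A `whale_pop` object.
#' @param ap An [acoustic_params()] object.
#' @param dive A [dive_params()] object.
#' @return Integer vector of detected group ids.
#' @export
detect_groups <- function(station_pos, w, ap, dive) {
  if (length(w$x) == 0L) return(integer(0))
  vocal <- is_vocalising(w, dive)
  d2 <- (w$x - station_pos[1])^2 + (w$y - station_pos[2])^2
  w$id[vocal & d2 <= ap$effective_range^2]
}

#' Measure a noisy acoustic bearing
#'
#' True bearing plus a Normal error with sd `bearing_sd` degrees, wrapped to
#' `[0, 360)`.
#'
#' @param station_pos,group_pos Length-2 numeric positions (km).
#' @param bearing_sd Degrees.
#' @return Bearing in degrees.
#' @export
measure_bearing <- function(station_pos, group_pos, bearing_sd) {
  (true_bearing(station_pos, group_pos) + stats::rnorm(1, 0, bearing_sd)) %% 360
}

#' Measure a noisy aural distance estimate (hydrophone workflow)
#'
#' Multiplicative error by default: `true * (1 + Normal(0, sd_frac))`, floored
#' at 0.1 km; with `additive = TRUE` the error is `Normal(0, sd_frac)` km.
#'
#' @param station_pos,group_pos Length-2 numeric positions (km).
#' @param distance_sd_frac Error CV (or additive sd in km).
#' @param additive Interpret the error additively?
#' @return Estimated distance, km.
#' @export
measure_distance <- function(station_pos, group_pos, distance_sd_frac,
                             additive = FALSE) {
  d <- sqrt(sum((group_pos - station_pos)^2))
  est <- if (additive) d + stats::rnorm(1, 0, distance_sd_frac)
         else d * (1 + stats::rnorm(1, 0, distance_sd_frac))
  max(0.1, est)
}

#' Intersect two bearing rays (cross-bearing fix)
#'
#' Intersection of the forward half-lines from two stations along their
#' bearings. Returns `NULL` when the rays are parallel, diverge (the
#' intersection lies behind either station), or the stations coincide. With
#' zero bearing noise and non-degenerate geometry the fix reproduces the true
#' source position exactly.
#'
#' @param p1,p2 Station positions, length-2 numeric (km).
#' @param brg1,brg2 Bearings from each station, degrees clockwise from north.
#' @return Length-2 numeric position, or `NULL`.
#' @export
cross_fix <- function(p1, brg1, p2, brg2) {
  if (all(p1 == p2)) return(NULL)
  u1 <- c(sin(brg1 * DEG), cos(brg1 * DEG))
  u2 <- c(sin(brg2 * DEG), cos(brg2 * DEG))
  det <- u1[1] * (-u2[2]) - (-u2[1]) * u1[2]
  if (abs(det) < 1e-12) return(NULL)
  b <- p2 - p1
  t1 <- (b[1] * (-u2[2]) - (-u2[1]) * b[2]) / det
  t2 <- (u1[1] * b[2] - b[1] * u1[2]) / det
  if (t1 <= 0 || t2 <= 0) return(NULL)
  p1 + t1 * u1
}

#' Update the sonobuoy field
#'
#' A buoy is active while it is younger than `buoy_life` and the vessel is
#' within `vhf_range` of it (buoys are not retrieved; an inactive buoy is never
#' reactivated).
#'
#' @param buoys List of parallel vectors `x, y, deploy_time, active`.
#' @param vessel_pos Length-2 numeric (km).
#' @param now Current time, h.
#' @param ap An [acoustic_params()] object.
#' @return The updated buoy list.
#' @export
update_sonobuoys <- function(buoys, vessel_pos, now, ap) {
  if (length(buoys$x) == 0L) return(buoys)
  d2 <- (buoys$x - vessel_pos[1])^2 + (buoys$y - vessel_pos[2])^2
  buoys$active <- buoys$active &
    (now - buoys$deploy_time < ap$buoy_life) & (d2 <= ap$vhf_range^2)
  buoys
}

#' Is a new listening station due?
#'
#' Hydrophone: a dip is due when the distance travelled since the last dip
#' reaches `dip_spacing`. Sonobuoy: a drop is due when the time since the last
#' drop reaches the mode's drop interval (`drop_interval_search` in naive
#' search, `drop_interval_target` while targeting).
#'
#' @param ap An [acoustic_params()] object.
#' @param since Distance travelled since the last dip (km, hydrophone) or time
#'   since the last drop (h, sonobuoy).
#' @param targeting Logical; is the vessel in targeted/direct mode?
#' @return Logical.
#' @export
due_for_station <- function(ap, since, targeting = FALSE) {
  if (ap$instrument == "hydrophone") {
    since >= ap$dip_spacing
  } else {
    since >= (if (targeting) ap$drop_interval_target else ap$drop_interval_search)
  }
}

#' Deterministic bearing-event accumulator
#'
#' Yields on average `bearings_per_hour * dt` bearing-update events per step by
#' fractional accumulation with remainder carry.
#'
#' @param carry Fractional remainder carried from the previous step.
#' @param dt Step length, h.
#' @param bearings_per_hour Event rate.
#' @return List with integer `n` (events this step) and the new `carry`.
#' @export
bearing_schedule <- function(carry, dt, bearings_per_hour) {
  stopifnot(dt > 0)
  acc <- carry + bearings_per_hour * dt
  n <- floor(acc + 1e-9)
  list(n = as.integer(n), carry = acc - n)
}
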