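#' Whale movement parameters
#'
#' Correlated-random-walk parameters for whale-group movement. At each time
#' step a wrapped-Normal increment is added to the heading and a multiplicative
#' Normal perturbation to the step length, so headings change smoothly through
#' time.
#'
#' @param speed_mean Mean swim speed, km/h.
#' @param turn_sd Standard deviation of the heading increment, degrees per
#'   reference 0.5-h step. For other step lengths `dt` the engine scales the
#'   increment sd by `sqrt(dt/0.5)` so the heading diffuses at the same rate.
#' @param distance_sd_frac Coefficient of variation of the per-step distance
#'   (unitless); step length is floored at zero.
#' @return An object of class `amr_movement`.
#' @export
movement_params <- function(speed_mean = 4.5, turn_sd = 30, distance_sd_frac = 0.2) {
  stopifnot(speed_mean >= 0, turn_sd >= 0, distance_sd_frac >= 0)
  structure(list(speed_mean = speed_mean, turn_sd = turn_sd,
                 distance_sd_frac = distance_sd_frac),
            class = "amr_movement")
}

#' Dive/vocalisation cycle parameters
#'
#' Alternating dive/surface phases with Normal durations (truncated at a small
#' positive floor). A group vocalises during the first
#' `vocal_fraction_of_dive` of each dive and is silent for the remainder of the
#' dive and while at the surface. When `enabled = FALSE` the cycle is ignored
#' and every vocal-capable group vocalises continuously (the baleen-whale
#' convention).
#'
#' @param enabled Logical; model the dive cycle at all?
#' @param dive_mean,dive_sd Dive duration mean and sd, minutes.
#' @param surface_mean,surface_sd Surface duration mean and sd, minutes.
#' @param vocal_fraction_of_dive Fraction of the dive (from its start) during
#'   which the group vocalises, in \[0, 1\].
#' @param floor_min Truncation floor for phase-duration draws, minutes.
#' @return An object of class `amr_dive`.
#' @export
dive_params <- function(enabled = FALSE, dive_mean = 41.3, dive_sd = 7,
                        surface_mean = 9.1, surface_sd = 2.5,
                        vocal_fraction_of_dive = 0.8, floor_min = 1) {
  if (enabled) stopifnot(dive_mean > 0, surface_mean > 0, dive_sd >= 0,
                         surface_sd >= 0, floor_min > 0)
  stopifnot(vocal_fraction_of_dive >= 0, vocal_fraction_of_dive <= 1)
  structure(list(enabled = isTRUE(enabled), dive_mean = dive_mean,
                 dive_sd = dive_sd, surface_mean = surface_mean,
                 surface_sd = surface_sd,
                 vocal_fraction_of_dive = vocal_fraction_of_dive,
                 floor_min = floor_min),
            class = "amr_dive")
}

#' Whale population parameters
#'
#' Abundance is driven either by a Normal draw of the group count
#' (`mode = "count"`) or by a fixed density over the survey area
#' (`mode = "density"`). Spatial distribution is either uniform or clumped;
#' clumped populations are placed as Gaussian scatters around uniformly placed
#' clump centres and move as blocks.
#'
#' @param mode `"count"` or `"density"`.
#' @param count_mean,count_sd Mean and sd of the number of groups (count mode).
#' @param density Groups per square km (density mode).
#' @param p_vocal Probability that a group is vocally capable at all.
#' @param distribution `"uniform"` or `"clumped"`.
#' @param clump_count Number of clumps, or `NA` to derive it from the realised
#'   group count as `ceiling(n / clump_mean_size)`.
#' @param clump_spread Isotropic Gaussian sd of member offsets about the clump
#'   centre, km.
#' @param clump_mean_size Target mean clump size used when `clump_count` is
#'   `NA`.
#' @return An object of class `amr_population`.
#' @export
population_params <- function(mode = c("count", "density"), count_mean = 10,
                              count_sd = 0, density = NA_real_, p_vocal = 1,
                              distribution = c("uniform", "clumped"),
                              clump_count = NA_integer_, clump_spread = 5,
                              clump_mean_size = 4) {
  mode <- match.arg(mode)
  distribution <- match.arg(distribution)
  stopifnot(p_vocal >= 0, p_vocal <= 1, clump_spread >= 0, clump_mean_size >= 1)
  if (mode == "density") stopifnot(is.finite(density), density >= 0)
  if (mode == "count") stopifnot(is.finite(count_mean), count_mean >= 0, count_sd >= 0)
  if (!is.na(clump_count)) stopifnot(clump_count >= 1)
  structure(list(mode = mode, count_mean = count_mean, count_sd = count_sd,
                 density = density, p_vocal = p_vocal,
                 distribution = distribution, clump_count = clump_count,
                 clump_spread = clump_spread, clump_mean_size = clump_mean_size),
            class = "amr_population")
}

#' Acoustic tracking system parameters
#'
#' Two instrument families are supported: hand-held directional hydrophones
#' (the vessel stops for a listening "dip" at regular distances and obtains one
#' bearing, with an aural distance estimate, per audible group) and DIFAR
#' sonobuoys (expendable drifting stations dropped at regular time intervals
#' that radio bearings to the vessel over VHF until they expire or the vessel
#' sails out of VHF range). Detection is a hard disc: every vocalising group
#' within `effective_range` of a station is detected, none beyond. The
#' effective range plays the role of an effective strip half-width.
#'
#' @param instrument `"hydrophone"` or `"sonobuoy"`.
#' @param effective_range Effective acoustic detection range, km.
#' @param bearing_sd Bearing measurement error sd, degrees.
#' @param distance_sd_frac Aural distance-estimate error (hydrophone only);
#'   multiplicative CV by default.
#' @param distance_additive If `TRUE`, interpret `distance_sd_frac` as an
#'   additive sd in km instead of a CV.
#' @param dip_spacing Distance between hydrophone dips, km.
#' @param dwell_time Hydrophone dwell (listening stop) duration, h.
#' @param buoy_life Sonobuoy transmission lifetime, h.
#' @param vhf_range Sonobuoy VHF reception range, km.
#' @param drop_interval_search,drop_interval_target Sonobuoy drop intervals in
#'   naive-search and targeted modes, h.
#' @param bearings_per_hour Bearing-update events per hour (sonobuoy).
#' @param max_sea_state Highest Beaufort sea state at which acoustics operate.
#' @return An object of class `amr_acoustics`.
#' @export
acoustic_params <- function(instrument = c("sonobuoy", "hydrophone"),
                            effective_range = 50, bearing_sd = 15,
                            distance_sd_frac = 0, distance_additive = FALSE,
                            dip_spacing = 3.6, dwell_time = 2 / 60,
                            buoy_life = 8, vhf_range = 18.52,
                            drop_interval_search = 4, drop_interval_target = 1,
                            bearings_per_hour = 6, max_sea_state = 5) {
  instrument <- match.arg(instrument)
  stopifnot(effective_range > 0, bearing_sd >= 0, buoy_life > 0, vhf_range > 0,
            dip_spacing > 0, dwell_time >= 0, drop_interval_search > 0,
            drop_interval_target > 0, bearings_per_hour >= 0,
            distance_sd_frac >= 0)
  structure(list(instrument = instrument, effective_range = effective_range,
                 bearing_sd = bearing_sd, distance_sd_frac = distance_sd_frac,
                 distance_additive = isTRUE(distance_additive),
                 dip_spacing = dip_spacing, dwell_time = dwell_time,
                 buoy_life = buoy_life, vhf_range = vhf_range,
                 drop_interval_search = drop_interval_search,
                 drop_interval_target = drop_interval_target,
                 bearings_per_hour = bearings_per_hour,
                 max_sea_state = max_sea_state),
            class = "amr_acoustics")
}

#' Survey vessel parameters
#'
#' @param speed Vessel speed, km/h.
#' @param visual_esw_half Visual effective strip half-width, km (hard strip).
#' @param g0 Probability of sighting an available group inside the strip.
#' @param time_to_mark Fixed marking duration, h (used when
#'   `mark_until_fluke = FALSE`, or as fallback).
#' @param mark_until_fluke If `TRUE`, marking lasts until the target's current
#'   surface phase ends (sperm-whale fluke-up convention); requires the dive
#'   cycle to be enabled, else falls back to `time_to_mark`.
#' @param p_abandon_per_hour Probability per hour that an ongoing tracking is
#'   abandoned; compounded per step as `1 - (1 - p)^dt`.
#' @param give_up_time Hours without a fresh bearing to the target before it is
#'   given up on.
#' @param max_tracking_time Maximum time a single group is tracked, h.
#' @param min_sightability Lowest sightability index at which the visual team
#'   operates.
#' @param dawn,dusk Daylight window (hour of day, half-open `[dawn, dusk)`).
#' @param corridor_half_width Half-width of the bearing-line corridor, km:
#'   within it the vessel runs parallel to the bearing, outside it the vessel
#'   steams to the closest point on the bearing line.
#' @param pending_staleness Hours after which an untracked prior detection is
#'   dropped from the revisit queue.
#' @param recognise_marked If `TRUE` the team can tell already-marked groups
#'   apart acoustically (long-term studies of known individuals) and never
#'   re-targets them; if `FALSE` bearings carry no identity, so marked groups
#'   are tracked like any other and are only recognised (and released, without
#'   logging a re-encounter) once sighted.
#' @return An object of class `amr_vessel`.
#' @export
vessel_params <- function(speed = 20.3, visual_esw_half = 3.5, g0 = 1,
                          time_to_mark = 1.51, mark_until_fluke = FALSE,
                          p_abandon_per_hour = 0, give_up_time = 3,
                          max_tracking_time = 14, min_sightability = 0,
                          dawn = 6, dusk = 18, corridor_half_width = 2,
                          pending_staleness = 6, recognise_marked = FALSE) {
  stopifnot(speed > 0, g0 >= 0, g0 <= 1, p_abandon_per_hour >= 0,
            p_abandon_per_hour <= 1, visual_esw_half >= 0, time_to_mark >= 0,
            give_up_time > 0, max_tracking_time > 0,
            dawn >= 0, dawn < 24, dusk >= 0, dusk <= 24,
            corridor_half_width > 0, pending_staleness > 0)
  structure(list(speed = speed, visual_esw_half = visual_esw_half, g0 = g0,
                 time_to_mark = time_to_mark,
                 mark_until_fluke = isTRUE(mark_until_fluke),
                 p_abandon_per_hour = p_abandon_per_hour,
                 give_up_time = give_up_time,
                 max_tracking_time = max_tracking_time,
                 min_sightability = min_sightability, dawn = dawn, dusk = dusk,
                 corridor_half_width = corridor_half_width,
                 pending_staleness = pending_staleness,
                 recognise_marked = isTRUE(recognise_marked)),
            class = "amr_vessel")
}

#' Weather model parameters
#'
#' A persistent (Markov) Beaufort sea-state series: the first state is drawn
#' from `stationary_weights`; each subsequent step keeps the current state with
#' probability `transition_persistence`, otherwise redraws from
#' `stationary_weights`. Sightability is an ordinal index derived from the sea
#' state via `sightability_from_state`. With `enabled = FALSE` every step has
#' sea state 0 and maximal sightability.
#'
#' @param enabled Logical.
#' @param state_levels Beaufort levels.
#' @param stationary_weights Marginal probabilities of the levels (sum to 1).
#' @param transition_persistence Probability of keeping the current state per
#'   step.
#' @param sightability_from_state Numeric vector parallel to `state_levels`
#'   giving the sightability index for each level.
#' @return An object of class `amr_weather`.
#' @export
weather_params <- function(enabled = FALSE, state_levels = 0:7,
                           stationary_weights = c(0.05, 0.10, 0.15, 0.20,
                                                  0.20, 0.15, 0.10, 0.05),
                           transition_persistence = 0.9,
                           sightability_from_state = pmax(0, 6 - (0:7))) {
  stopifnot(length(state_levels) == length(stationary_weights),
            length(sightability_from_state) == length(state_levels),
            all(stationary_weights >= 0),
            abs(sum(stationary_weights) - 1) < 1e-8,
            transition_persistence >= 0, transition_persistence <= 1)
  structure(list(enabled = isTRUE(enabled), state_levels = state_levels,
                 stationary_weights = stationary_weights,
                 transition_persistence = transition_persistence,
                 sightability_from_state = sightability_from_state),
            class = "amr_weather")
}

#' Assemble a survey configuration
#'
#' Bundles all component parameter sets with the survey-level settings into a
#' single validated configuration object consumed by [run_survey()].
#'
#' @param area Numeric length-2, survey rectangle width and height in km
#'   (planar coordinates, origin at the SW corner; headings in degrees
#'   clockwise from north).
#' @param duration Survey duration, h.
#' @param dt Time step, h; must divide `duration`.
#' @param survey_mode `"AMR"` (acoustically assisted mark-recapture), `"VMR"`
#'   (visual-only mark-recapture) or `"LT"` (visual line transect).
#' @param overnight_acoustics If `TRUE` acoustics operate around the clock;
#'   otherwise they follow the daylight window.
#' @param start_hour Hour of day at which the survey starts.
#' @param pop,move,dive,ac,ves,wx Component parameter objects (see
#'   [population_params()], [movement_params()], [dive_params()],
#'   [acoustic_params()], [vessel_params()], [weather_params()]).
#' @param label Optional scenario label carried into result tables.
#' @return An object of class `amr_config`.
#' @export
survey_config <- function(area = c(400, 400), duration = 240, dt = 0.5,
                          survey_mode = c("AMR", "VMR", "LT"),
                          overnight_acoustics = TRUE, start_hour = 6,
                          pop = population_params(), move = movement_params(),
                          dive = dive_params(), ac = acoustic_params(),
                          ves = vessel_params(), wx = weather_params(),
                          label = "scenario") {
  survey_mode <- match.arg(survey_mode)
  cfg <- structure(list(area = as.numeric(area), duration = duration, dt = dt,
                        survey_mode = survey_mode,
                        overnight_acoustics = isTRUE(overnight_acoustics),
                        start_hour = start_hour, pop = pop, move = move,
                        dive = dive, ac = ac, ves = ves, wx = wx,
                        label = label),
                   class = "amr_config")
  validate_config(cfg)
}

#' Validate a survey configuration
#'
#' Checks the cross-field invariants of an [survey_config()] object and returns
#' it invisibly unchanged; stops with a message naming the offending key
#' otherwise.
#'
#' @param cfg An `amr_config` object.
#' @return `cfg`, invisibly (but also visibly usable in a pipeline).
#' @export
validate_config <- function(cfg) {
  fail <- function(key, msg) stop("invalid configuration: `", key, "` ", msg,
                                  call. = FALSE)
  if (length(cfg$area) != 2 || any(!is.finite(cfg$area)) || any(cfg$area <= 0))
    fail("area", "must be two positive dimensions (km)")
  if (!is.finite(cfg$dt) || cfg$dt <= 0) fail("dt", "must be > 0")
  if (!is.finite(cfg$duration) || cfg$duration <= 0)
    fail("duration", "must be > 0")
  n_steps <- cfg$duration / cfg$dt
  if (abs(n_steps - round(n_steps)) > 1e-6)
    fail("dt", "must divide duration")
  if (!inherits(cfg$pop, "amr_population")) fail("pop", "is not population_params()")
  if (!inherits(cfg$move, "amr_movement")) fail("move", "is not movement_params()")
  if (!inherits(cfg$dive, "amr_dive")) fail("dive", "is not dive_params()")
  if (!inherits(cfg$ac, "amr_acoustics")) fail("ac", "is not acoustic_params()")
  if (!inherits(cfg$ves, "amr_vessel")) fail("ves", "is not vessel_params()")
  if (!inherits(cfg$wx, "amr_weather")) fail("wx", "is not weather_params()")
  if (cfg$pop$mode == "density" && !is.finite(cfg$pop$density))
    fail("pop.density", "must be set in density mode")
  if (cfg$ves$dusk <= cfg$ves$dawn) fail("ves.dusk", "must be after dawn")
  invisible(cfg)
}

#' @export
print.amr_config <- function(x, ...) {
  cat("<amr_config> ", x$label, "\n", sep = "")
  cat(sprintf("  area %.5g x %.5g km, duration %g h, dt %g h, mode %s\n",
              x$area[1], x$area[2], x$duration, x$dt, x$survey_mode))
  ab <- if (x$pop$mode == "density")
    sprintf("density %g groups/km2", x$pop$density)
  else sprintf("count ~ Normal(%g, %g)", x$pop$count_mean, x$pop$count_sd)
  cat(sprintf("  whales: %s, %s, p_vocal %g, speed %g km/h\n", ab,
              x$pop$distribution, x$pop$p_vocal, x$move$speed_mean))
  cat(sprintf("  acoustics: %s, range %g km, bearing sd %g deg\n",
              x$ac$instrument, x$ac$effective_range, x$ac$bearing_sd))
  cat(sprintf("  vessel: %g km/h, ESW/2 %g km, g0 %g\n",
              x$ves$speed, x$ves$visual_esw_half, x$ves$g0))
  invisible(x)
}
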