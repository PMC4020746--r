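# Whale-group population: initialisation, correlated-random-walk movement with
# boundary reversal, clumped block movement, and the dive/vocalisation cycle.
# The population is a list of parallel vectors (class "whale_pop") so that the
# engine can advance all groups with vectorised arithmetic.

DEG <- pi / 180

#' Initialise a whale-group population
#'
#' Draws the number of groups (Normal count rounded to a non-negative integer,
#' or `round(density * area)`), places them uniformly or in Gaussian clumps
#' around uniform clump centres (clipped to the area), assigns independent
#' vocal capability with probability `p_vocal`, uniform initial headings, and
#' (when the dive cycle is enabled) random initial phases entered at a uniform
#' point of their duration.
#'
#' @param pop A [population_params()] object.
#' @param area Length-2 numeric, survey rectangle (km).
#' @param dive A [dive_params()] object (used to seed dive phases).
#' @return A `whale_pop` object: list of parallel vectors `id, x, y, heading,
#'   vocal_capable, diving, phase_elapsed, phase_duration, clump, encountered`
#'   plus per-clump headings.
#' @export
init_population <- function(pop, area, dive = dive_params()) {
  if (length(area) != 2 || any(area <= 0))
    stop("invalid configuration: `area` must be positive", call. = FALSE)
  n <- if (pop$mode == "count") {
    max(0L, as.integer(round(stats::rnorm(1, pop$count_mean, pop$count_sd))))
  } else {
    as.integer(round(pop$density * area[1] * area[2]))
  }
  w <- list(id = seq_len(n), x = numeric(n), y = numeric(n),
            heading = stats::runif(n, 0, 360),
            vocal_capable = stats::runif(n) < pop$p_vocal,
            diving = rep(FALSE, n), phase_elapsed = numeric(n),
            phase_duration = rep(Inf, n), clump = rep(NA_integer_, n),
            encountered = rep(FALSE, n), clump_heading = numeric(0))
  if (pop$distribution == "uniform" || n == 0L) {
    w$x <- stats::runif(n, 0, area[1])
    w$y <- stats::runif(n, 0, area[2])
  } else {
    k <- if (is.na(pop$clump_count)) max(1L, as.integer(ceiling(n / pop$clump_mean_size)))
         else as.integer(pop$clump_count)
    k <- min(k, n)  # no empty clumps
    cx <- stats::runif(k, 0, area[1])
    cy <- stats::runif(k, 0, area[2])
    w$clump <- sort(rep_len(seq_len(k), n))
    w$x <- pmin(pmax(cx[w$clump] + stats::rnorm(n, 0, pop$clump_spread), 0), area[1])
    w$y <- pmin(pmax(cy[w$clump] + stats::rnorm(n, 0, pop$clump_spread), 0), area[2])
    w$clump_heading <- stats::runif(k, 0, 360)
    csize <- tabulate(w$clump, nbins = k)
    w$clump_cx <- drop(rowsum(w$x, w$clump)) / csize
    w$clump_cy <- drop(rowsum(w$y, w$clump)) / csize
  }
  if (dive$enabled && n > 0L) {
    # start each group at a uniformly random point of a random phase, weighted
    # by mean phase duration so the process starts near stationarity
    p_dive <- dive$dive_mean / (dive$dive_mean + dive$surface_mean)
    w$diving <- stats::runif(n) < p_dive
    w$phase_duration <- draw_phase(n, w$diving, dive)
    w$phase_elapsed <- stats::runif(n) * w$phase_duration
  }
  class(w) <- "whale_pop"
  w
}

# truncated-Normal phase duration draw, hours
draw_phase <- function(n, diving, dive) {
  mu <- ifelse(diving, dive$dive_mean, dive$surface_mean)
  sd <- ifelse(diving, dive$dive_sd, dive$surface_sd)
  pmax(dive$floor_min, stats::rnorm(n, mu, sd)) / 60
}

#' Reflect candidate positions at the survey boundary
#'
#' Whale groups reaching the survey boundary reverse direction, turning back
#' into the area: if a candidate step exits the rectangle the heading is
#' reversed (+180 degrees) and the position clamped to the boundary; interior
#' positions pass through unchanged. Vectorised.
#'
#' @param x,y Candidate positions (km).
#' @param heading Headings, degrees clockwise from north.
#' @param area Length-2 numeric (km).
#' @return List with elements `x`, `y`, `heading`.
#' @export
reflect_at_boundary <- function(x, y, heading, area) {
  out <- x < 0 | x > area[1] | y < 0 | y > area[2]
  if (any(out)) {
    heading[out] <- (heading[out] + 180) %% 360
    x <- pmin(pmax(x, 0), area[1])
    y <- pmin(pmax(y, 0), area[2])
  }
  list(x = x, y = y, heading = heading)
}

#' Advance independent whale groups one correlated-random-walk step
#'
#' Each group's heading receives a Normal increment with sd
#' `turn_sd * sqrt(dt / 0.5)` (so the heading diffusion rate is independent of
#' the step size) and the step length is
#' `max(0, speed_mean * dt * (1 + Normal(0, distance_sd_frac)))`; the boundary
#' reversal rule is then applied.
#'
#' @param w A `whale_pop` object (groups without a clump id, or any population
#'   to be moved independently).
#' @param dt Time step, h.
#' @param mp A [movement_params()] object.
#' @param area Length-2 numeric (km).
#' @return The advanced `whale_pop`.
#' @export
step_movement <- function(w, dt, mp, area) {
  n <- length(w$x)
  if (n == 0L) return(w)
  w$heading <- (w$heading + stats::rnorm(n, 0, mp$turn_sd * sqrt(dt / 0.5))) %% 360
  len <- pmax(0, mp$speed_mean * dt * (1 + stats::rnorm(n, 0, mp$distance_sd_frac)))
  r <- reflect_at_boundary(w$x + len * sin(w$heading * DEG),
                           w$y + len * cos(w$heading * DEG), w$heading, area)
  w$x <- r$x; w$y <- r$y; w$heading <- r$heading
  w
}

#' Advance a clumped population one step (block movement)
#'
#' One correlated-random-walk step is drawn per clump and applied identically
#' to all its members, so the clump moves as a block and within-clump pairwise
#' distances are preserved away from boundaries. Boundary reversal is applied
#' at clump level using the clump centroid; individual members are then clamped
#' to the survey rectangle.
#'
#' @inheritParams step_movement
#' @return The advanced `whale_pop`.
#' @export
step_clumped <- function(w, dt, mp, area) {
  if (length(w$x) == 0L) return(w)
  if (anyNA(w$clump))
    stop("invalid configuration: clumped stepping requires clump ids", call. = FALSE)
  k <- length(w$clump_heading)
  w$clump_heading <- (w$clump_heading +
                        stats::rnorm(k, 0, mp$turn_sd * sqrt(dt / 0.5))) %% 360
  len <- pmax(0, mp$speed_mean * dt * (1 + stats::rnorm(k, 0, mp$distance_sd_frac)))
  dx <- len * sin(w$clump_heading * DEG)
  dy <- len * cos(w$clump_heading * DEG)
  # centroid-level reversal: if a clump centroid would exit, reverse the clump
  # (centroids are carried incrementally; members are clamped individually)
  cx <- w$clump_cx + dx
  cy <- w$clump_cy + dy
  rev <- cx < 0 | cx > area[1] | cy < 0 | cy > area[2]
  if (any(rev)) {
    w$clump_heading[rev] <- (w$clump_heading[rev] + 180) %% 360
    dx[rev] <- -dx[rev]
    dy[rev] <- -dy[rev]
    cx <- w$clump_cx + dx
    cy <- w$clump_cy + dy
  }
  w$clump_cx <- cx
  w$clump_cy <- cy
  w$x <- pmin(pmax(w$x + dx[w$clump], 0), area[1])
  w$y <- pmin(pmax(w$y + dy[w$clump], 0), area[2])
  w$heading <- w$clump_heading[w$clump]
  w
}

#' Advance the dive/vocalisation cycle
#'
#' Phase clocks advance by `dt`; groups exceeding their phase duration flip
#' phase (dive to surface and vice versa) and draw a new truncated-Normal
#' duration. Disabled cycles leave the population untouched.
#'
#' @param w A `whale_pop` object.
#' @param dt Time step, h.
#' @param dive A [dive_params()] object.
#' @return The advanced `whale_pop`.
#' @export
update_dive_state <- function(w, dt, dive) {
  if (!dive$enabled || length(w$x) == 0L) return(w)
  w$phase_elapsed <- w$phase_elapsed + dt
  flip <- w$phase_elapsed >= w$phase_duration
  if (any(flip)) {
    w$diving[flip] <- !w$diving[flip]
    w$phase_elapsed[flip] <- 0
    w$phase_duration[flip] <- draw_phase(sum(flip), w$diving[flip], dive)
  }
  w
}

#' Which groups are vocalising now?
#'
#' A group vocalises iff it is vocal-capable and, when the dive cycle is
#' enabled, it is in the dive phase with less than `vocal_fraction_of_dive` of
#' the dive elapsed (sperm whales click for all but the last part of a dive and
#' are silent at the surface). With the cycle disabled every vocal-capable
#' group vocalises continuously.
#'
#' @param w A `whale_pop` object.
#' @param dive A [dive_params()] object.
#' @return Logical vector over groups.
#' @export
is_vocalising <- function(w, dive) {
  if (!dive$enabled) return(w$vocal_capable)
  w$vocal_capable & w$diving &
    w$phase_elapsed < dive$vocal_fraction_of_dive * w$phase_duration
}

# one whole-population movement step, dispatching on distribution
step_population <- function(w, dt, mp, area, clumped) {
  if (clumped) step_clumped(w, dt, mp, area) else step_movement(w, dt, mp, area)
}
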