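# Vessel navigation and decision helpers: systematic naive-search grid,
# bearing-line (targeted) and cross-fix (direct) navigation, the hard-strip
# visual detection model, abandonment and marking-time rules. The per-step
# state machine itself lives in the survey engine.

#' Create a naive-search coverage grid
#'
#' The survey rectangle is divided into cells of side about
#' `2 * visual_esw_half` (so a swept cell approximates a visually searched
#' cell); the vessel heads for unvisited cells and the grid resets when all
#' cells have been visited.
#'
#' @param area Length-2 numeric (km).
#' @param cell Target cell side, km.
#' @return A `search_grid` list: cell centres and a visited flag per cell.
#' @export
search_grid <- function(area, cell) {
  nx <- max(1L, as.integer(round(area[1] / cell)))
  ny <- max(1L, as.integer(round(area[2] / cell)))
  cw <- area[1] / nx
  ch <- area[2] / ny
  cx <- rep((seq_len(nx) - 0.5) * cw, times = ny)
  cy <- rep((seq_len(ny) - 0.5) * ch, each = nx)
  list(nx = nx, ny = ny, cw = cw, ch = ch, cx = cx, cy = cy,
       visited = rep(FALSE, nx * ny))
}

# index of the grid cell containing a position
grid_cell_at <- function(grid, x, y) {
  ix <- pmin(grid$nx, pmax(1L, 1L + floor(x / grid$cw)))
  iy <- pmin(grid$ny, pmax(1L, 1L + floor(y / grid$ch)))
  as.integer((iy - 1L) * grid$nx + ix)
}

#' Naive-search heading: nearest unvisited cell
#'
#' Returns the heading toward the centre of the nearest unvisited cell, with a
#' boustrophedon tie-break (prefer cells in the vessel's current row, then
#' cells ahead in the current sweep direction). When all cells are visited the
#' grid resets and the search restarts.
#'
#' @param grid A [search_grid()] (with current `visited` flags).
#' @param pos Vessel position, length-2 numeric.
#' @param sweep_sign +1 when sweeping east, -1 when sweeping west (tie-break).
#' @return List with `heading` (degrees), `cell` (target cell index) and the
#'   possibly reset `grid`.
#' @export
naive_search_heading <- function(grid, pos, sweep_sign = 1) {
  if (all(grid$visited)) grid$visited[] <- FALSE
  open <- which(!grid$visited)
  dx <- grid$cx[open] - pos[1]
  dy <- grid$cy[open] - pos[2]
  d2 <- dx * dx + dy * dy
  best <- d2 <= min(d2) + 1e-9
  cand <- open[best]
  if (length(cand) > 1L) {
    # prefer the current row, then the cell ahead in the sweep direction
    row_pen <- abs(grid$cy[cand] - pos[2])
    ahead <- sign(grid$cx[cand] - pos[1]) == sweep_sign
    ord <- order(row_pen, !ahead, grid$cx[cand] * sweep_sign)
    cand <- cand[ord]
  }
  cell <- cand[1]
  tgt <- c(grid$cx[cell], grid$cy[cell])
  hd <- if (all(tgt == pos)) 0 else true_bearing(pos, tgt)
  list(heading = hd, cell = cell, grid = grid)
}

#' Heading while following a single acoustic bearing
#'
#' If the vessel lies within `corridor_half_width` of the bearing ray (the
#' forward half-line from the station along the bearing) it runs parallel to
#' the bearing; otherwise it steams toward the closest point on the ray.
#'
#' @param vessel_pos,station_pos Length-2 numeric (km).
#' @param bearing_deg Bearing from the station, degrees clockwise from north.
#' @param corridor_half_width Corridor half-width, km.
#' @return Heading in degrees.
#' @export
targeted_heading <- function(vessel_pos, station_pos, bearing_deg,
                             corridor_half_width = 2) {
  u <- c(sin(bearing_deg * DEG), cos(bearing_deg * DEG))
  v <- vessel_pos - station_pos
  t <- max(0, sum(v * u))           # projection onto the ray, clamped
  foot <- station_pos + t * u
  off <- sqrt(sum((vessel_pos - foot)^2))
  if (off <= corridor_half_width) bearing_deg
  else true_bearing(vessel_pos, foot)
}

#' Heading straight to a cross-bearing fix
#'
#' @param vessel_pos,fix_pos Length-2 numeric (km).
#' @return Heading in degrees; `NA` when the vessel is at the fix (hold
#'   position and attempt visual detection).
#' @export
direct_heading <- function(vessel_pos, fix_pos) {
  if (all(vessel_pos == fix_pos)) return(NA_real_)
  true_bearing(vessel_pos, fix_pos)
}

#' Attempt visual detection (hard strip)
#'
#' Under workable conditions, each not-yet-encountered group within
#' `visual_esw_half` of the vessel is sighted with probability `g0`. When the
#' dive-cycle model is enabled, diving groups are unavailable to observers;
#' without a dive cycle availability is subsumed in `g0`.
#'
#' @param vessel_pos Length-2 numeric (km).
#' @param w A `whale_pop` object.
#' @param vp A [vessel_params()] object.
#' @param dive A [dive_params()] object.
#' @param env_ok_visual Logical: daylight/sightability/sea-state gate.
#' @return Integer vector of sighted group ids.
#' @export
attempt_visual_detection <- function(vessel_pos, w, vp, dive, env_ok_visual) {
  if (!env_ok_visual || length(w$x) == 0L) return(integer(0))
  d2 <- (w$x - vessel_pos[1])^2 + (w$y - vessel_pos[2])^2
  avail <- !w$encountered & d2 <= vp$visual_esw_half^2
  if (dive$enabled) avail <- avail & !w$diving
  if (!any(avail)) return(integer(0))
  ids <- w$id[avail]
  if (vp$g0 >= 1) ids else ids[stats::runif(length(ids)) < vp$g0]
}

#' Per-step abandonment decision
#'
#' Tracking is abandoned with per-step probability `1 - (1 - p)^dt`, i.e. a
#' constant hazard of `p_abandon_per_hour`, so the longer a group is tracked
#' the greater the chance its tracking is aborted.
#'
#' @param dt Step, h.
#' @param p_abandon_per_hour Probability per hour.
#' @return Logical.
#' @export
check_abandon <- function(dt, p_abandon_per_hour) {
  if (p_abandon_per_hour <= 0) return(FALSE)
  stats::runif(1) < 1 - (1 - p_abandon_per_hour)^dt
}

#' Marking duration for a sighted target
#'
#' With `mark_until_fluke` and an enabled dive cycle, marking lasts until the
#' target's current surface phase ends (photo-identification completes at
#' fluke-up); otherwise a fixed `time_to_mark` is used.
#'
#' @param vp A [vessel_params()] object.
#' @param w A `whale_pop` object.
#' @param target_idx Index (row) of the sighted target group in `w`.
#' @param dive A [dive_params()] object.
#' @return Marking time, h.
#' @export
marking_duration <- function(vp, w, target_idx, dive) {
  if (vp$mark_until_fluke && dive$enabled && !w$diving[target_idx]) {
    max(0, w$phase_duration[target_idx] - w$phase_elapsed[target_idx])
  } else {
    vp$time_to_mark
  }
}
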