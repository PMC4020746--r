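# Scenario presets, replicate batteries, density grids, sensitivity sweeps and
# fold-improvement summaries.

#' Derive a replicate seed from a root seed
#'
#' Deterministic Lehmer-style hash of `(root, cell, rep)`, kept below 2^31 so
#' it is a valid R integer seed. Sweep results are therefore invariant to cell
#' execution order.
#'
#' @param root Root integer seed.
#' @param cell Cell index (e.g. position in a sweep grid).
#' @param rep Replicate index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, cell = 0L, rep = 1L) {
  m <- 2147483647
  s <- (abs(root) %% m)
  s <- (s * 48271 + cell + 1) %% m
  s <- (s * 48271 + rep + 1) %% m
  as.integer(s + 1)
}

#' Kaikoura sperm-whale scenario preset
#'
#' The validation scenario: a small-boat acoustically assisted photo-ID survey
#' of sperm whales off Kaikoura, New Zealand. Hand-held directional hydrophone
#' dips every 3.6 km (2-min dwell), effective acoustic range 5.556 km, bearing
#' error sd 28.7 degrees, aural distance-estimate CV 0.49; whale count drawn
#' from Normal(13.8, 1.3) over an 18.52 x 37.04 km rectangle; swim speed
#' 5.04 km/h; dive cycle Normal(41.3, 7) min dives and Normal(9.1, 2.5) min
#' surfacings, vocal for all but the last 20% of each dive, silent at the
#' surface; all groups vocal-capable. Vessel 37 km/h, visual ESW/2 2 km,
#' g0 = 1, marking until fluke-up (end of the surface phase), give-up 2 h, max
#' tracking 4 h. One survey day is 7.033 h at a 2-min step; weather is off.
#'
#' @param distribution `"clumped"` or `"uniform"`.
#' @param survey_mode `"AMR"`, `"VMR"` or `"LT"`.
#' @return An [survey_config()] object.
#' @export
preset_kaikoura <- function(distribution = c("clumped", "uniform"),
                            survey_mode = "AMR") {
  distribution <- match.arg(distribution)
  survey_config(
    area = c(18.52, 37.04), duration = 7.033, dt = 7.033 / 211,
    survey_mode = survey_mode, overnight_acoustics = TRUE, start_hour = 8,
    pop = population_params(mode = "count", count_mean = 13.8, count_sd = 1.3,
                            p_vocal = 1, distribution = distribution,
                            clump_spread = 2, clump_mean_size = 4),
    move = movement_params(speed_mean = 5.04, turn_sd = 30,
                           distance_sd_frac = 0.2),
    dive = dive_params(enabled = TRUE, dive_mean = 41.3, dive_sd = 7,
                       surface_mean = 9.1, surface_sd = 2.5,
                       vocal_fraction_of_dive = 0.8),
    ac = acoustic_params(instrument = "hydrophone", effective_range = 5.556,
                         bearing_sd = 28.7, distance_sd_frac = 0.49,
                         dip_spacing = 3.6, dwell_time = 2 / 60,
                         max_sea_state = 5),
    ves = vessel_params(speed = 37, visual_esw_half = 2.0, g0 = 1,
                        time_to_mark = 9.1 / 60, mark_until_fluke = TRUE,
                        p_abandon_per_hour = 0, give_up_time = 2,
                        max_tracking_time = 4, min_sightability = 0,
                        dawn = 6, dusk = 18,
                        # a prior detection goes stale once the whale could
                        # have left acoustic range (range / swim speed);
                        # resident whales are individually known, so marked
                        # ones are recognised acoustically and not re-tracked
                        pending_staleness = 1.1, recognise_marked = TRUE),
    wx = weather_params(enabled = FALSE),
    label = "kaikoura")
}

#' Antarctic blue-whale scenario preset
#'
#' The prediction scenario: a large-vessel DIFAR-sonobuoy survey of Antarctic
#' blue whales. Density 0.000539957 groups/km2 over a 400 x 400 km area, 60%
#' of groups vocal (continuously, once vocal), swim speed 4.5 km/h. Sonobuoys:
#' effective range 50 km, 8-h transmission life, 18.52 km VHF range, bearing
#' error sd 15 degrees, drop intervals 4 h searching / 1 h targeting, 6
#' bearings per hour, acoustics up to Beaufort 5 and around the clock. Vessel
#' 20.3 km/h, visual ESW/2 3.5 km, g0 = 1, marking 1.51 h, abandonment
#' 0.02/h, give-up 3 h, max tracking 14 h, visual team needs sightability >= 2
#' and daylight (06:00-18:00). Ten days (240 h) at a 0.5-h step with the
#' synthetic weather model on.
#'
#' @param distribution `"clumped"` or `"uniform"`.
#' @param survey_mode `"AMR"`, `"VMR"` or `"LT"`.
#' @param density Groups per km2.
#' @return An [survey_config()] object.
#' @export
preset_antarctic <- function(distribution = c("clumped", "uniform"),
                             survey_mode = "AMR", density = 0.000539957) {
  distribution <- match.arg(distribution)
  survey_config(
    area = c(400, 400), duration = 240, dt = 0.5,
    survey_mode = survey_mode, overnight_acoustics = TRUE, start_hour = 6,
    pop = population_params(mode = "density", density = density, p_vocal = 0.6,
                            distribution = distribution, clump_spread = 4,
                            clump_mean_size = 10),
    move = movement_params(speed_mean = 4.5, turn_sd = 30,
                           distance_sd_frac = 0.2),
    dive = dive_params(enabled = FALSE),
    ac = acoustic_params(instrument = "sonobuoy", effective_range = 50,
                         bearing_sd = 15, buoy_life = 8, vhf_range = 18.52,
                         drop_interval_search = 4, drop_interval_target = 1,
                         bearings_per_hour = 6, max_sea_state = 5),
    ves = vessel_params(speed = 20.3, visual_esw_half = 3.5, g0 = 1,
                        time_to_mark = 1.51, mark_until_fluke = FALSE,
                        p_abandon_per_hour = 0.02, give_up_time = 3,
                        max_tracking_time = 14, min_sightability = 2,
                        dawn = 6, dusk = 18),
    wx = weather_params(enabled = TRUE),
    label = "antarctic")
}

#' Default density grid for blue-whale batteries
#'
#' Log-spaced grid spanning 0.0002-0.002 groups/km2 around the extrapolated
#' current Antarctic blue whale density.
#'
#' @param n Number of grid points.
#' @param lo,hi Grid limits, groups/km2.
#' @return Numeric vector.
#' @export
default_density_grid <- function(n = 5, lo = 2e-4, hi = 2e-3) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Run a battery of independent survey replicates
#'
#' `n_reps` replicates of `cfg` with seeds derived from `(seed, cell, rep)`;
#' returns a one-row summary of the encounter-rate distribution.
#'
#' @param cfg An [survey_config()] object.
#' @param n_reps Number of replicates.
#' @param seed Root seed.
#' @param cell Cell index used in seed derivation (for sweeps).
#' @return A one-row data frame of class `amr_battery`: scenario, survey mode,
#'   density (or `NA` in count mode), mean/median/variance of the per-replicate
#'   encounter rate, mean acoustic and visual rates, mean buoys used, `n_reps`
#'   and the Monte Carlo standard error `mc_se = sd/sqrt(n_reps)`. The
#'   per-replicate rates are attached as attribute `"reps"`.
#' @export
run_battery <- function(cfg, n_reps, seed = 1, cell = 0L) {
  stopifnot(n_reps >= 1)
  rate <- arate <- vrate <- buoys <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    res <- run_survey(cfg, derive_seed(seed, cell, r))
    rate[r] <- res$encounter_rate
    arate[r] <- res$acoustic_rate
    vrate[r] <- res$visual_rate
    buoys[r] <- res$buoys_used
  }
  out <- data.frame(scenario = cfg$label, survey_mode = cfg$survey_mode,
                    density = if (cfg$pop$mode == "density") cfg$pop$density else NA_real_,
                    mean_rate = mean(rate), median_rate = stats::median(rate),
                    var_rate = if (n_reps > 1) stats::var(rate) else 0,
                    mean_acoustic_rate = mean(arate),
                    mean_visual_rate = mean(vrate),
                    mean_buoys = mean(buoys), n_reps = n_reps,
                    mc_se = if (n_reps > 1) stats::sd(rate) / sqrt(n_reps) else 0,
                    stringsAsFactors = FALSE)
  attr(out, "reps") <- data.frame(rep = seq_len(n_reps), rate = rate,
                                  acoustic_rate = arate, visual_rate = vrate,
                                  buoys_used = buoys)
  class(out) <- c("amr_battery", "data.frame")
  out
}

#' Run a battery over a density grid
#'
#' @param cfg Base [survey_config()] (density mode).
#' @param densities Numeric vector of densities.
#' @param n_reps Replicates per density.
#' @param seed Root seed.
#' @param cell0 Offset added to the cell index in seed derivation, so paired
#'   experiments can share (`cell0` equal) or avoid (`cell0` different) common
#'   random numbers across the grid.
#' @return An `amr_battery` data frame with one row per density.
#' @export
run_density_grid <- function(cfg, densities, n_reps, seed = 1, cell0 = 0L) {
  rows <- lapply(seq_along(densities), function(i) {
    ci <- cfg
    ci$pop$density <- densities[i]
    run_battery(ci, n_reps, seed, cell = cell0 + i)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("amr_battery", "data.frame")
  out
}

# resolve/assign a dotted parameter path like "ac.effective_range"
set_config_value <- function(cfg, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref <- cfg
  for (k in keys) {
    if (is.null(ref[[k]])) stop("unknown parameter path: ", path, call. = FALSE)
    ref <- ref[[k]]
  }
  expr <- paste0("cfg", paste0("[['", keys, "']]", collapse = ""), " <- value")
  eval(parse(text = expr))
  validate_config(cfg)
  cfg
}

#' Sensitivity sweep over one parameter and a density grid
#'
#' Full factorial over `values x densities`, `reps_per_cell` replicates each;
#' seeds are derived from `(seed, cell_index, rep)`, so results do not depend
#' on execution order.
#'
#' @param cfg Base [survey_config()] object.
#' @param parameter_path Dotted config key, e.g. `"ac.effective_range"` or
#'   `"pop.p_vocal"`.
#' @param values Values to sweep.
#' @param densities Density grid (use `NA` to keep the base abundance
#'   settings).
#' @param reps_per_cell Replicates per cell.
#' @param seed Root seed.
#' @return An `amr_battery` data frame with a `value` column, one row per
#'   (value, density) cell.
#' @export
sweep_parameter <- function(cfg, parameter_path, values,
                            densities = NA_real_, reps_per_cell = 100,
                            seed = 1) {
  stopifnot(length(values) >= 1, reps_per_cell >= 1)
  cells <- expand.grid(vi = seq_along(values), di = seq_along(densities))
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    cc <- set_config_value(cfg, parameter_path, values[cells$vi[ci]])
    if (!is.na(cells$di[ci]) && !is.na(densities[cells$di[ci]]))
      cc$pop$density <- densities[cells$di[ci]]
    out <- run_battery(cc, reps_per_cell, seed, cell = ci)
    out$value <- values[cells$vi[ci]]
    out
  })
  out <- do.call(rbind, rows)
  out$parameter <- parameter_path
  class(out) <- c("amr_battery", "data.frame")
  out
}

#' Fold improvement of one battery over a baseline
#'
#' Per-density ratio of mean encounter rates, with delta-method Monte Carlo
#' standard errors. Densities must match; a zero baseline mean yields `NA`
#' (undefined), never infinity.
#'
#' @param amr An `amr_battery` (e.g. the acoustically assisted runs).
#' @param baseline An `amr_battery` on the same density grid.
#' @return Data frame with `density`, `ratio` and `ratio_se`.
#' @export
fold_improvement <- function(amr, baseline) {
  stopifnot(nrow(amr) == nrow(baseline))
  if (!isTRUE(all.equal(amr$density, baseline$density)))
    stop("density grids do not match", call. = FALSE)
  ratio <- ifelse(baseline$mean_rate > 0, amr$mean_rate / baseline$mean_rate,
                  NA_real_)
  # delta method for a ratio of independent means
  se <- ifelse(baseline$mean_rate > 0,
               abs(ratio) * sqrt((amr$mc_se / amr$mean_rate)^2 +
                                   (baseline$mc_se / baseline$mean_rate)^2),
               NA_real_)
  data.frame(density = amr$density, ratio = ratio, ratio_se = se)
}

#' @export
print.amr_battery <- function(x, ...) {
  cat("<amr_battery> ", nrow(x), " cell(s)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Plot mean encounter rate against density
#'
#' Base-graphics summary of a density-grid battery: mean total rate with the
#' acoustic-track component shaded beneath it.
#'
#' @param x An `amr_battery` over a density grid.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.amr_battery <- function(x, ...) {
  graphics::plot(x$density, x$mean_rate, type = "b", pch = 19,
                 xlab = "density (groups/km2)",
                 ylab = "mean encounter rate (/h)", ...)
  if (any(x$mean_acoustic_rate > 0)) {
    graphics::lines(x$density, x$mean_acoustic_rate, type = "b", pch = 1,
                    lty = 2)
    graphics::legend("topleft", legend = c("total", "acoustic track"),
                     lty = c(1, 2), pch = c(19, 1), bty = "n")
  }
  invisible(x)
}
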