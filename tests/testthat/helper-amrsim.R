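# Shared helpers: small configurations and a lazy cache so expensive replicate
# batteries are computed once and reused across test blocks.

.amr_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .amr_cache, inherits = FALSE))
    assign(name, force(expr), envir = .amr_cache)
  get(name, envir = .amr_cache, inherits = FALSE)
}

# a fast, featureless configuration for plumbing tests
quick_config <- function(survey_mode = "AMR", ...) {
  survey_config(area = c(50, 50), duration = 12, dt = 0.5,
                survey_mode = survey_mode,
                pop = population_params(mode = "count", count_mean = 5,
                                        count_sd = 0, p_vocal = 1),
                move = movement_params(speed_mean = 4.5),
                dive = dive_params(enabled = FALSE),
                ac = acoustic_params(instrument = "sonobuoy",
                                     effective_range = 20, bearing_sd = 5),
                ves = vessel_params(speed = 20, visual_esw_half = 2,
                                    give_up_time = 2, max_tracking_time = 6),
                wx = weather_params(enabled = FALSE), ...)
}

# per-day rate tables for the sperm-whale validation batteries
kaikoura_days <- function(distribution, n_days, seed, mode = "AMR") {
  run_day_sequence(preset_kaikoura(distribution, survey_mode = mode),
                   n_days, seed = seed)
}

blue_grid_battery <- function(mode = "AMR", distribution = "clumped",
                              n_reps = 300, seed = 101,
                              overnight = TRUE) {
  cfg <- preset_antarctic(distribution, survey_mode = mode)
  cfg$overnight_acoustics <- overnight
  run_density_grid(cfg, default_density_grid(), n_reps, seed = seed)
}

blue_point_battery <- function(mode = "AMR", n_reps = 300, seed = 202) {
  run_battery(preset_antarctic("clumped", survey_mode = mode), n_reps,
              seed = seed)
}
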