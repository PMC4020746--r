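test_that("an empty ocean yields no encounters in any survey mode", {
  for (m in c("AMR", "VMR", "LT")) {
    cfg <- quick_config(survey_mode = m)
    cfg$pop$count_mean <- 0
    r <- run_survey(cfg, seed = 1)
    expect_identical(nrow(r$encounters), 0L)
    expect_identical(r$encounter_rate, 0)
  }
})

test_that("equal seeds reproduce a replicate bit-identically", {
  for (cfg in list(quick_config(), preset_kaikoura("clumped"),
                   preset_antarctic("clumped"))) {
    a <- run_survey(cfg, seed = 77)
    b <- run_survey(cfg, seed = 77)
    expect_identical(a, b)
  }
})

test_that("encounter sources partition the total and groups are unique", {
  cfgs <- list(preset_kaikoura("clumped"),
               preset_antarctic("clumped", density = 2e-3))
  for (cfg in cfgs) {
    for (s in 1:5) {
      r <- run_survey(cfg, seed = s)
      n_ac <- sum(r$encounters$source == "acoustic_track")
      n_vis <- sum(r$encounters$source == "incidental_visual")
      expect_identical(n_ac + n_vis, nrow(r$encounters))
      expect_equal(r$acoustic_rate + r$visual_rate, r$encounter_rate)
      expect_false(any(duplicated(r$encounters$group)))
      expect_identical(r$total_hours, cfg$duration)
      expect_true(all(r$encounters$time > 0 & r$encounters$time <= cfg$duration))
      expect_true(all(r$encounters$x >= 0 & r$encounters$x <= cfg$area[1]))
    }
  }
})

test_that("encounters are classified by the vessel's current target", {
  expect_identical(classify_encounter(3L, "TARGETED", 3L), "acoustic_track")
  expect_identical(classify_encounter(3L, "DIRECT", 3L), "acoustic_track")
  expect_identical(classify_encounter(4L, "TARGETED", 3L), "incidental_visual")
  expect_identical(classify_encounter(3L, "NAIVE", NA_integer_),
                   "incidental_visual")
})

test_that("a day sequence redraws the population independently each day", {
  cfg <- preset_kaikoura("clumped")
  d <- run_day_sequence(cfg, 8, seed = 3)
  expect_identical(nrow(d), 8L)
  expect_true(length(unique(d$seed)) == 8L)
  expect_true(sd(d$n_groups) > 0)              # count redrawn from its Normal
  expect_equal(d$rate, d$encounters / 7.033)
  # one day equals a single survey with the same derived seed
  r1 <- run_survey(cfg, derive_seed(3, 0L, 1L))
  expect_identical(d$encounters[1], nrow(r1$encounters))
})

test_that("the optional track log records every tick without changing results", {
  cfg <- preset_antarctic("clumped")
  rt <- run_survey(cfg, seed = 9, track = TRUE)
  expect_identical(nrow(rt$track), as.integer(cfg$duration / cfg$dt))
  expect_true(all(rt$track$mode %in% c("NAIVE", "TARGETED", "DIRECT",
                                       "MARKING")))
  expect_true(all(rt$track$x >= 0 & rt$track$x <= cfg$area[1]))
  rt$track <- NULL
  expect_identical(rt, run_survey(cfg, seed = 9))
  expect_output(summary(rt), "mode hours")
})

test_that("buoy consumption is conserved and only AMR uses acoustics", {
  cfg <- preset_antarctic("clumped")
  r <- run_survey(cfg, seed = 4)
  expect_gt(r$buoys_used, 0)
  rv <- run_survey(preset_antarctic("clumped", survey_mode = "VMR"), seed = 4)
  expect_identical(rv$buoys_used, 0L)
  expect_identical(sum(rv$encounters$source == "acoustic_track"), 0L)
  rl <- run_survey(preset_antarctic("clumped", survey_mode = "LT"), seed = 4)
  expect_identical(sum(rl$encounters$source == "acoustic_track"), 0L)
})
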