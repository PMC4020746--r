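test_that("naive search heads for the nearest unvisited cell and resets", {
  g <- search_grid(c(20, 40), 4)
  ns <- naive_search_heading(g, c(0, 0))
  # from the SW corner the first target is the corner cell of the south row
  expect_equal(ns$cell, 1L)
  expect_lt(abs(ns$heading - true_bearing(c(0, 0), c(g$cx[1], g$cy[1]))), 1e-9)
  # all visited: the grid resets and the search restarts
  g$visited[] <- TRUE
  ns2 <- naive_search_heading(g, c(10, 20))
  expect_false(all(ns2$grid$visited))
  expect_true(ns2$cell %in% seq_along(g$visited))
})

test_that("bearing-line navigation follows or closes on the ray", {
  # on the ray: run parallel to the bearing
  expect_equal(targeted_heading(c(0, 5), c(0, 0), 0, 2), 0)
  # far abeam: head perpendicular toward the ray
  expect_equal(targeted_heading(c(10, 5), c(0, 0), 0, 2), 270)
  # randomised: the returned heading never increases distance to the ray and
  # either closes on it or advances along it
  set.seed(11)
  for (i in 1:200) {
    st <- runif(2, -50, 50); brg <- runif(1, 0, 360); v <- runif(2, -50, 50)
    hd <- targeted_heading(v, st, brg, 2)
    u <- c(sin(brg * pi / 180), cos(brg * pi / 180))
    step <- 0.5
    v2 <- v + step * c(sin(hd * pi / 180), cos(hd * pi / 180))
    perp <- function(p) {
      t <- max(0, sum((p - st) * u)); sqrt(sum((p - (st + t * u))^2))
    }
    along <- function(p) max(0, sum((p - st) * u))
    expect_true(perp(v2) <= perp(v) + 1e-9 ||
                  along(v2) > along(v) + 1e-9)
  }
  expect_equal(direct_heading(c(0, 0), c(0, 10)), 0)
  expect_equal(direct_heading(c(0, 0), c(10, 0)), 90)
  expect_true(is.na(direct_heading(c(3, 3), c(3, 3))))
})

test_that("visual detection is a gated hard strip with availability", {
  vp <- vessel_params(speed = 20.3, visual_esw_half = 3.5, g0 = 1)
  dc_off <- dive_params(enabled = FALSE)
  w <- init_population(population_params(mode = "count", count_mean = 2,
                                         count_sd = 0), c(100, 100), dc_off)
  w$x <- c(52, 60); w$y <- c(50, 50)       # 2 km and 10 km from the vessel
  expect_identical(attempt_visual_detection(c(50, 50), w, vp, dc_off, TRUE), 1L)
  # darkness / bad conditions suppress everything
  expect_identical(attempt_visual_detection(c(50, 50), w, vp, dc_off, FALSE),
                   integer(0))
  # g0 = 0 never sights
  vp0 <- vessel_params(visual_esw_half = 3.5, g0 = 0)
  set.seed(12)
  expect_identical(attempt_visual_detection(c(50, 50), w, vp0, dc_off, TRUE),
                   integer(0))
  # diving sperm whales are unavailable to observers
  dc_on <- dive_params(enabled = TRUE)
  w$diving <- c(TRUE, FALSE)
  expect_identical(attempt_visual_detection(c(50, 50), w, vp, dc_on, TRUE),
                   integer(0))
  # already-encountered groups are never re-sighted
  w$diving <- c(FALSE, FALSE); w$encountered <- c(TRUE, FALSE)
  expect_identical(attempt_visual_detection(c(50, 50), w, vp, dc_on, TRUE),
                   integer(0))
})

test_that("abandonment compounds the hourly hazard over the step", {
  expect_false(check_abandon(1, 0))
  set.seed(13)
  p_step <- mean(replicate(4e4, check_abandon(0.5, 0.02)))
  expected <- 1 - 0.98^0.5                  # ~ 0.01005
  expect_lt(abs(p_step - expected), 3 * sqrt(expected * (1 - expected) / 4e4))
})

test_that("marking lasts until fluke-up for divers and a fixed time otherwise", {
  dc <- dive_params(enabled = TRUE)
  w <- init_population(population_params(mode = "count", count_mean = 1,
                                         count_sd = 0), c(10, 10), dc)
  w$diving <- FALSE; w$phase_duration <- 9 / 60; w$phase_elapsed <- 5 / 60
  vp_fluke <- vessel_params(time_to_mark = 1.51, mark_until_fluke = TRUE)
  expect_equal(marking_duration(vp_fluke, w, 1, dc), 4 / 60)  # 4 min left
  vp_fixed <- vessel_params(time_to_mark = 1.51, mark_until_fluke = FALSE)
  expect_equal(marking_duration(vp_fixed, w, 1, dc), 1.51)
  # fluke-up rule falls back to the fixed time without a dive cycle
  expect_equal(marking_duration(vp_fluke, w, 1, dive_params(enabled = FALSE)),
               1.51)
})
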