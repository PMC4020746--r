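test_that("population initialisation matches abundance and vocal fractions", {
  set.seed(1)
  # density mode: count is deterministic given area
  pop <- population_params(mode = "density", density = 0.000539957)
  w <- init_population(pop, c(500, 500))
  expect_equal(length(w$x), 135L)  # round(0.000539957 * 250000)
  # degenerate vocal probability
  expect_true(all(init_population(population_params(mode = "count",
    count_mean = 50, count_sd = 0, p_vocal = 1), c(10, 10))$vocal_capable))
  # binomial oracle for the vocal fraction
  wv <- init_population(population_params(mode = "count", count_mean = 10000,
    count_sd = 0, p_vocal = 0.6), c(100, 100))
  mc_sd <- sqrt(0.6 * 0.4 / 10000)
  expect_lt(abs(mean(wv$vocal_capable) - 0.6), 3 * mc_sd)
  # positions inside the rectangle, uniform and clumped
  wc <- init_population(population_params(mode = "count", count_mean = 200,
    count_sd = 0, distribution = "clumped", clump_spread = 5), c(30, 30))
  expect_true(all(wc$x >= 0 & wc$x <= 30 & wc$y >= 0 & wc$y <= 30))
  expect_false(anyNA(wc$clump))
  expect_error(init_population(pop, c(-1, 10)), "area")
})

test_that("correlated random walk moves as specified", {
  area <- c(1000, 1000)
  # deterministic step: due east at 4.5 km/h for 0.5 h
  w <- init_population(population_params(mode = "count", count_mean = 1,
                                         count_sd = 0), area)
  w$x <- 500; w$y <- 500; w$heading <- 90
  w2 <- step_movement(w, 0.5, movement_params(4.5, turn_sd = 0,
                                              distance_sd_frac = 0), area)
  expect_equal(w2$x, 502.25, tolerance = 1e-12)
  expect_equal(w2$y, 500, tolerance = 1e-12)
  expect_equal(w2$heading, 90)
  # zero speed: position fixed under any randomness
  set.seed(2)
  w3 <- step_movement(w, 0.5, movement_params(0, turn_sd = 30,
                                              distance_sd_frac = 0.5), area)
  expect_equal(w3$x, w$x)
  expect_equal(w3$y, w$y)
  # sample-moment oracle for the heading increment spread at dt = 0.5
  set.seed(3)
  n <- 1e5
  wb <- init_population(population_params(mode = "count", count_mean = n,
                                          count_sd = 0), area)
  h0 <- wb$heading
  wb <- step_movement(wb, 0.5, movement_params(0, turn_sd = 10,
                                               distance_sd_frac = 0), area)
  inc <- (wb$heading - h0 + 180) %% 360 - 180
  expect_lt(abs(sd(inc) - 10), 3 * 10 / sqrt(2 * n))
})

test_that("boundary reversal turns groups back into the area", {
  area <- c(10, 20)
  r <- reflect_at_boundary(5, 21, 0, area)     # exited the north edge
  expect_equal(r$heading, 180)
  expect_equal(r$y, 20)
  r2 <- reflect_at_boundary(5, 10, 123, area)  # interior: identity
  expect_equal(r2$heading, 123)
  expect_equal(r2$x, 5)
  # containment over a long trajectory
  set.seed(4)
  w <- init_population(population_params(mode = "count", count_mean = 1000,
                                         count_sd = 0), c(5, 5))
  for (i in 1:1000) {
    w <- step_movement(w, 0.5, movement_params(4.5, 30, 0.2), c(5, 5))
    if (any(w$x < 0 | w$x > 5 | w$y < 0 | w$y > 5))
      fail("position escaped the survey rectangle")
  }
  succeed()
})

test_that("clumped stepping moves blocks rigidly away from boundaries", {
  set.seed(5)
  area <- c(1e5, 1e5)
  w <- init_population(population_params(mode = "count", count_mean = 20,
    count_sd = 0, distribution = "clumped", clump_count = 4,
    clump_spread = 2), area)
  d0 <- dist(cbind(w$x, w$y))
  for (i in 1:1000) w <- step_clumped(w, 0.5, movement_params(4.5, 30, 0.2), area)
  # pairwise distances within clumps preserved (interior of a huge area)
  same <- outer(w$clump, w$clump, "==")[lower.tri(diag(20))]
  expect_equal(as.vector(dist(cbind(w$x, w$y)))[same], as.vector(d0)[same],
               tolerance = 1e-8)
  # one step: members of one clump share the displacement, clumps differ
  x0 <- w$x; y0 <- w$y
  w <- step_clumped(w, 0.5, movement_params(4.5, 30, 0.2), area)
  dx <- round(w$x - x0, 10); dy <- round(w$y - y0, 10)
  expect_equal(length(unique(paste(dx, dy))), length(unique(w$clump)))
  expect_error(step_clumped(init_population(population_params(
    mode = "count", count_mean = 3, count_sd = 0), area), 0.5,
    movement_params(), area), "clump")
})

test_that("dive cycle alternates phases with the stated stationary fractions", {
  dc <- dive_params(enabled = TRUE, dive_mean = 41.3, dive_sd = 7,
                    surface_mean = 9.1, surface_sd = 2.5,
                    vocal_fraction_of_dive = 0.8)
  # disabled cycle never changes state
  w <- init_population(population_params(mode = "count", count_mean = 5,
                                         count_sd = 0), c(10, 10),
                       dive_params(enabled = FALSE))
  w1 <- update_dive_state(w, 0.5, dive_params(enabled = FALSE))
  expect_identical(w1$diving, w$diving)
  expect_identical(w1$phase_elapsed, w$phase_elapsed)
  # renewal oracle: long-run diving fraction = 41.3 / (41.3 + 9.1)
  set.seed(6)
  wd <- init_population(population_params(mode = "count", count_mean = 500,
                                          count_sd = 0), c(10, 10), dc)
  dt <- 2 / 60
  frac <- 0
  nstep <- 3000
  for (i in seq_len(nstep)) {
    wd <- update_dive_state(wd, dt, dc)
    frac <- frac + mean(wd$diving)
  }
  expect_lt(abs(frac / nstep - 41.3 / 50.4), 0.015)
  # vocal only while diving and before 80% of the dive has elapsed
  wd$diving <- c(TRUE, TRUE, FALSE, rep(TRUE, 497))
  wd$phase_duration <- rep(1, 500)
  wd$phase_elapsed <- c(0.5, 0.9, 0.1, rep(0.5, 497))
  v <- is_vocalising(wd, dc)
  expect_true(v[1])    # mid-dive
  expect_false(v[2])   # silent tail of the dive
  expect_false(v[3])   # silent at the surface
  wd$vocal_capable[4] <- FALSE
  expect_false(is_vocalising(wd, dc)[4])
  # disabled cycle: every vocal-capable group vocalises
  expect_identical(is_vocalising(wd, dive_params(enabled = FALSE)),
                   wd$vocal_capable)
})

test_that("identical seeds give bit-identical trajectories", {
  run <- function() {
    set.seed(42)
    w <- init_population(population_params(mode = "count", count_mean = 30,
      count_sd = 2, distribution = "clumped", clump_spread = 3), c(50, 50),
      dive_params(enabled = TRUE))
    for (i in 1:50) {
      w <- step_clumped(w, 0.5, movement_params(4.5, 30, 0.2), c(50, 50))
      w <- update_dive_state(w, 0.5, dive_params(enabled = TRUE))
    }
    w
  }
  expect_identical(run(), run())
})
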