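test_that("hard-disc detection depends only on range and vocal state", {
  ap <- acoustic_params(instrument = "hydrophone", effective_range = 5.556)
  dc <- dive_params(enabled = FALSE)
  w <- init_population(population_params(mode = "count", count_mean = 3,
                                         count_sd = 0, p_vocal = 1), c(100, 100))
  w$x <- c(50, 50, 50); w$y <- c(55, 80, 51)   # 5, 30, 1 km from the station
  w$vocal_capable <- c(TRUE, TRUE, FALSE)
  det <- detect_groups(c(50, 50), w, ap, dc)
  expect_identical(det, 1L)                     # in range and vocalising
  ap2 <- acoustic_params(effective_range = 50)
  w$y <- c(55, 110, 51)                         # 5, 60, 1 km
  expect_identical(detect_groups(c(50, 50), w, ap2, dc), 1L)
})

test_that("bearing and distance measurements follow their error models", {
  expect_equal(measure_bearing(c(0, 0), c(0, 5), 0), 0)
  expect_equal(measure_bearing(c(0, 0), c(5, 0), 0), 90)
  expect_error(measure_bearing(c(1, 1), c(1, 1), 0), "coincident")
  set.seed(7)
  b <- replicate(2e4, measure_bearing(c(0, 0), c(0, 5), 28.7))
  inc <- (b + 180) %% 360 - 180
  expect_lt(abs(sd(inc) - 28.7), 1)            # circular ~ linear sd here
  expect_equal(measure_distance(c(0, 0), c(3, 0), 0), 3)
  set.seed(8)
  d <- replicate(2e4, measure_distance(c(0, 0), c(10, 0), 0.49))
  expect_lt(abs(sd(d / 10) - 0.49), 0.03)      # CV oracle (floor negligible)
  # floor: a draw implying a negative distance returns 0.1 km
  set.seed(9)
  dd <- replicate(200, measure_distance(c(0, 0), c(0.11, 0), 0.49))
  expect_true(all(dd >= 0.1))
})

test_that("cross-bearing fixes intersect forward rays only", {
  expect_equal(cross_fix(c(0, 0), 45, c(10, 0), 315), c(5, 5),
               tolerance = 1e-10)
  expect_null(cross_fix(c(0, 0), 0, c(10, 0), 0))      # parallel
  expect_null(cross_fix(c(0, 0), 0, c(0, 0), 90))      # coincident stations
  # randomised oracle: with zero bearing noise the fix recovers the source,
  # and reversed bearings (rays pointing away) return nothing
  set.seed(10)
  for (i in 1:200) {
    s1 <- runif(2, 0, 100); s2 <- runif(2, 0, 100); src <- runif(2, 0, 100)
    if (all(s1 == s2)) next
    b1 <- true_bearing(s1, src); b2 <- true_bearing(s2, src)
    fx <- cross_fix(s1, b1, s2, b2)
    if (!is.null(fx)) expect_equal(fx, src, tolerance = 1e-6)
    expect_null(cross_fix(s1, (b1 + 180) %% 360, s2, (b2 + 180) %% 360))
  }
})

test_that("sonobuoys deactivate on expiry or VHF loss and never reactivate", {
  ap <- acoustic_params(buoy_life = 8, vhf_range = 18.52)
  b <- list(x = c(0, 0, 0), y = c(0, 0, 0), deploy_time = c(0, 0, 8.4),
            active = c(TRUE, TRUE, TRUE))
  # age 8.5 > 8 h expires the first two; the third is fresh
  b1 <- update_sonobuoys(b, c(0, 0), 8.5, ap)
  expect_identical(b1$active, c(FALSE, FALSE, TRUE))
  # vessel 20 km away exceeds the 18.52 km VHF range
  b2 <- update_sonobuoys(b, c(20, 0), 1, ap)
  expect_identical(b2$active, c(FALSE, FALSE, FALSE))
  # a deactivated buoy stays off even if the vessel comes back
  b3 <- update_sonobuoys(b2, c(0, 0), 1.1, ap)
  expect_identical(b3$active, c(FALSE, FALSE, FALSE))
  # fresh buoy alongside is active
  expect_true(update_sonobuoys(list(x = 0, y = 0, deploy_time = 0,
                                    active = TRUE), c(0, 0), 0.1, ap)$active)
})

test_that("station scheduling follows dip spacing and drop intervals", {
  hyd <- acoustic_params(instrument = "hydrophone", dip_spacing = 3.6)
  expect_true(due_for_station(hyd, 3.7))
  expect_false(due_for_station(hyd, 0.2))
  sb <- acoustic_params(drop_interval_search = 4, drop_interval_target = 1)
  expect_false(due_for_station(sb, 0.5, targeting = TRUE))
  expect_true(due_for_station(sb, 1.0, targeting = TRUE))
  expect_false(due_for_station(sb, 3.5, targeting = FALSE))
  expect_true(due_for_station(sb, 4.0, targeting = FALSE))
})

test_that("bearing accumulator yields the exact long-run event rate", {
  expect_identical(bearing_schedule(0, 0.5, 6)$n, 3L)
  expect_identical(bearing_schedule(0, 0.5, 0)$n, 0L)
  carry <- 0; total <- 0L
  for (i in 1:5) {
    s <- bearing_schedule(carry, 0.2, 6)
    carry <- s$carry; total <- total + s$n
  }
  expect_identical(total, 6L)
})
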