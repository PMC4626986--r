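# toy scenario on a straight 10-cell road, hub+hospital at cell 0, one town
# hub at cell 0, hospital at the far end (cell n-1)
toy_scenario <- function(n = 10, congestion_factor = 1, ...) {
  g <- data.frame(row = 0L, col = 0:(n - 1), minutes = 1,
                  hub = c(TRUE, rep(FALSE, n - 1)),
                  hospital = c(rep(FALSE, n - 1), TRUE))
  ems_scenario(
    name = "toy", grid = ems_grid(g),
    towns = data.frame(town = "T", row = 0L, col = 2L, population = 1000),
    accident_rates = tibble::tibble(road = character(), month = integer(),
                                    lambda = numeric()),
    road_cells = tibble::tibble(road = "R1", row = 0L, col = 0:(n - 1)),
    weather_events = tibble::tibble(event = c("static", "rain", "snow", "fog", "ice"),
                                    duration = c(720, 120, 240, 120, 240),
                                    factor = c(1, 2, 3, 3, 4)),
    weather_days = tibble::tibble(event = rep(c("rain", "snow", "fog", "ice"), each = 12),
                                  month = rep(1:12, 4), days = 0),
    hotel_stays = rep(0, 12),
    festivity_days = tibble::tibble(type = rep(c("local_events", "roads_closed"), each = 12),
                                    month = rep(1:12, 2), days = 0L),
    horizon_days = 7, replications = 2, thresholds = c(2, 5, 10),
    congestion_factor = congestion_factor, ...)
}

test_that("a quiet system reproduces the static indicators with full availability", {
  sc <- quiet_avila(horizon_days = 14)
  r <- simulate_ems(sc, seed = 3, rep = 1)
  st <- static_indicators(sc)
  expect_equal(r$phi$phi, st$phi$phi, tolerance = 1e-9)
  expect_equal(r$availability, 1)
  occ <- r$occupation
  expect_equal(occ$fraction[occ$stage == "free"], 1)
  pi_w <- dplyr::inner_join(r$town_pi, st$town_pi, by = c("town", "k"))
  expect_equal(pi_w$pi.x, pi_w$pi.y, tolerance = 1e-9)
})

test_that("one scripted accident produces the hand-computed six-task cycle", {
  sc <- toy_scenario()
  scene <- cell_id_at(sc$grid, 0, 5)
  acc <- scripted_accident(time = 1000, cell = scene,
                           prep = 10, on_scene = 30, at_hospital = 15)
  r <- simulate_ems(sc, seed = 1, rep = 1, accidents = acc,
                    weather = no_overlays())
  a <- r$accidents
  # hub -> scene is 5 cells at 1 min; the hospital is 4 more cells out, and
  # the return leg home is the full 9 cells
  expect_equal(a$assigned, 1000)
  expect_equal(a$scene_arrival, 1000 + 10 + 5)
  expect_equal(a$scene_departure, 1000 + 10 + 5 + 30)
  expect_equal(a$cleared, 1000 + 10 + 5 + 30 + 4 + 15 + 9)
  expect_equal(a$response, 15)
  # the unit's stage intervals tile the horizon exactly
  iv <- r$intervals[r$intervals$unit == 1, ]
  expect_equal(sum(iv$end - iv$start), sc$horizon_days * 1440)
  busy <- iv[iv$stage != "free", ]
  expect_equal(sum(busy$end - busy$start), 10 + 5 + 30 + 4 + 15 + 9)
})

test_that("congestion around the scene doubles the affected part of the route", {
  sc <- toy_scenario(congestion_factor = 2)
  scene <- cell_id_at(sc$grid, 0, 5)
  acc <- scripted_accident(time = 1000, cell = scene, prep = 10,
                           on_scene = 30, at_hospital = 15)
  r <- simulate_ems(sc, seed = 1, rep = 1, accidents = acc,
                    weather = no_overlays())
  # cells 4,5,6 are congested: edge costs hub -> scene become
  # 1,1,1,(1+2)/2,(2+2)/2 = 6.5 min
  expect_equal(r$accidents$scene_arrival, 1000 + 10 + 6.5)
  # scene(5) -> hospital(9): 2,1.5,1,1 = 5.5; the return leg 9 -> 0 departs
  # 20.5 min after the scene, still inside the 60-min congestion window:
  # 1,1,1.5,2,2,1.5,1,1,1 = 12
  expect_equal(r$accidents$cleared - r$accidents$scene_departure, 5.5 + 15 + 12)
})

test_that("with one unit a second simultaneous accident waits for the full return", {
  sc <- toy_scenario()
  scene <- cell_id_at(sc$grid, 0, 5)
  acc <- rbind(
    scripted_accident(time = 1000, cell = scene, prep = 10, on_scene = 30,
                      at_hospital = 15, id = 1L),
    scripted_accident(time = 1001, cell = cell_id_at(sc$grid, 0, 3), prep = 8,
                      on_scene = 25, at_hospital = 12, id = 2L))
  r <- simulate_ems(sc, seed = 1, rep = 1, accidents = acc,
                    weather = no_overlays())
  a <- r$accidents
  expect_equal(a$assigned[2], a$cleared[1])
  expect_equal(a$scene_arrival[2], a$cleared[1] + 8 + 3)
  expect_equal(a$cleared[1], 1000 + 10 + 5 + 30 + 4 + 15 + 9)
  # with two units the second accident is served at once by unit 2
  r2 <- simulate_ems(sc, seed = 1, rep = 1, ambulances = 2, accidents = acc,
                     weather = no_overlays())
  expect_equal(r2$accidents$assigned[2], 1001)
  expect_equal(r2$accidents$unit, c(1L, 2L))
  expect_true(all(r2$accidents$response <= a$response + 1e-9))
})

test_that("dispatch prefers the closest free unit and breaks ties by id", {
  sc <- toy_scenario()
  acc <- scripted_accident(time = 100, cell = cell_id_at(sc$grid, 0, 4))
  r <- simulate_ems(sc, seed = 1, rep = 1, ambulances = 3, accidents = acc,
                    weather = no_overlays())
  expect_equal(r$accidents$unit, 1L)
})

test_that("runs are replayable: identical seeds give identical results", {
  sc <- make_avila_scenario(horizon_days = 20)
  r1 <- simulate_ems(sc, seed = 9, rep = 1)
  r2 <- simulate_ems(sc, seed = 9, rep = 1)
  expect_identical(r1$accidents, r2$accidents)
  expect_identical(r1$phi, r2$phi)
  expect_identical(r1$intervals, r2$intervals)
})

test_that("stage conservation holds on random scenarios", {
  for (seed in c(2, 5, 8)) {
    sc <- make_random_scenario(seed, horizon_days = 10)
    r <- simulate_ems(sc, seed = seed, rep = 1, ambulances = 2)
    for (u in 1:2) {
      iv <- r$intervals[r$intervals$unit == u, ]
      expect_equal(sum(iv$end - iv$start), sc$horizon_days * 1440,
                   tolerance = 1e-9)
    }
    sums <- tapply(r$occupation$fraction, r$occupation$unit, sum)
    expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)
  }
})

test_that("replication: n = 1 mean equals the single run; CRN dominance in c", {
  sc <- make_random_scenario(4, horizon_days = 15)
  reps1 <- replicate_ems(sc, replications = 1, seed = 6)
  single <- simulate_ems(sc, seed = 6, rep = 1)
  expect_equal(reps1$phi_mean$phi, single$phi$phi)
  # same seeds, more units: no accident responds later, coverage not lower
  r1 <- replicate_ems(sc, replications = 3, seed = 6, ambulances = 1)
  r2 <- replicate_ems(sc, replications = 3, seed = 6, ambulances = 2)
  for (i in 1:3) {
    d <- r2$runs[[i]]$accidents$response - r1$runs[[i]]$accidents$response
    expect_true(all(d <= 1e-9, na.rm = TRUE))
  }
  expect_true(all(r2$phi_mean$phi >= r1$phi_mean$phi - 1e-9))
})

test_that("unreachable accident cells are flagged uncoverable, not dropped", {
  sc <- toy_scenario()
  far <- cell_id_at(sc$grid, 0, 9)
  # sever the last cell from the road
  sc$grid$adj[[far]] <- integer(0)
  sc$grid$adj[[cell_id_at(sc$grid, 0, 8)]] <- cell_id_at(sc$grid, 0, 7)
  acc <- scripted_accident(time = 500, cell = far)
  expect_warning(
    r <- simulate_ems(sc, seed = 1, rep = 1, accidents = acc,
                      weather = no_overlays()),
    "uncoverable")
  expect_true(r$accidents$uncoverable)
  expect_equal(r$availability, 1)
})
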