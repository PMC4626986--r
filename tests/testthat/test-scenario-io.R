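test_that("the bundled scenario loads with the documented shape", {
  dir <- withr::local_tempdir()
  make_avila_scenario(path = dir)
  sc <- load_scenario(dir)
  expect_equal(sc$ambulances, 1L)
  expect_equal(length(unique(sc$accident_rates$road)), 18)
  expect_equal(sum(!sc$towns$settlement), 6)
  expect_equal(sc$thresholds, c(10, 20, 30, 40, 50, 60))
})

test_that("write -> load round-trips a scenario exactly", {
  for (build in list(function() make_avila_scenario(),
                     function() make_random_scenario(31))) {
    sc <- build()
    dir <- withr::local_tempdir()
    write_scenario(sc, dir)
    sc2 <- load_scenario(dir)
    expect_equal(sc2$towns, sc$towns)
    expect_equal(sc2$accident_rates[order(sc2$accident_rates$road,
                                          sc2$accident_rates$month), ],
                 sc$accident_rates[order(sc$accident_rates$road,
                                         sc$accident_rates$month), ],
                 ignore_attr = TRUE)
    expect_equal(sc2$grid$minutes, sc$grid$minutes)
    expect_equal(sc2$grid$hub, sc$grid$hub)
    expect_equal(sc2$hotel_stays, sc$hotel_stays)
    expect_equal(sc2$weather_events, sc$weather_events)
    expect_equal(sc2$thresholds, sc$thresholds)
    expect_equal(sc2$seed, sc$seed)
    expect_equal(sc2$stress_multiplier, sc$stress_multiplier)
    # a reloaded scenario simulates identically
    r1 <- simulate_ems(sc, seed = 4, rep = 1,
                       ambulances = 1)
    r2 <- simulate_ems(sc2, seed = 4, rep = 1, ambulances = 1)
    expect_equal(r1$phi, r2$phi)
  }
})

test_that("missing tables and invalid values raise named errors", {
  dir <- withr::local_tempdir()
  make_avila_scenario(path = dir)
  file.remove(file.path(dir, "meteorology.csv"))
  expect_error(load_scenario(dir), "meteorology.csv",
               class = "ems_missing_table_error")

  dir2 <- withr::local_tempdir()
  make_avila_scenario(path = dir2)
  we <- read.csv(file.path(dir2, "weather_events.csv"), check.names = FALSE)
  we[we$Event == "Penalty factor", "Snow"] <- 0.5
  write.csv(we, file.path(dir2, "weather_events.csv"), row.names = FALSE)
  expect_error(load_scenario(dir2), "snow", class = "ems_validation_error")

  dir3 <- withr::local_tempdir()
  make_avila_scenario(path = dir3)
  ac <- read.csv(file.path(dir3, "accidents.csv"), check.names = FALSE)
  ac[ac$Roads == "N-110", "MAR"] <- -2
  write.csv(ac, file.path(dir3, "accidents.csv"), row.names = FALSE)
  expect_error(load_scenario(dir3), "N-110/MAR", class = "ems_validation_error")
})

test_that("an empty accident table is a valid zero-load scenario", {
  dir <- withr::local_tempdir()
  make_avila_scenario(path = dir)
  writeLines(paste(c("Roads", emscover:::MONTHS3), collapse = ","),
             file.path(dir, "accidents.csv"))
  sc <- load_scenario(dir)
  expect_equal(nrow(sc$accident_rates), 0)
  cal <- emscover:::sample_accident_calendar(sc, master = 1, rep = 1)
  expect_equal(nrow(cal), 0)
})

test_that("indicator export is lossless and refuses non-results", {
  sc <- make_random_scenario(8, horizon_days = 10)
  reps <- replicate_ems(sc, replications = 2, seed = 3)
  dir <- withr::local_tempdir()
  export_indicators(reps, dir)
  back <- read_indicators(dir)
  expect_identical(back$phi$phi[back$phi$rep == "mean"], reps$phi_mean$phi)
  expect_identical(back$phi$phi[back$phi$rep == "1"], reps$runs[[1]]$phi$phi)
  expect_identical(back$town_pi$pi, reps$town_pi_mean$pi)
  expect_identical(back$occupation$fraction, reps$occupation_mean$fraction)
  expect_error(export_indicators(list(phi = 1), dir),
               class = "ems_validation_error")
})

test_that("static coverage export carries the full-coverage row", {
  sc <- quiet_avila(horizon_days = 7)
  r <- simulate_ems(sc, seed = 1, rep = 1)
  dir <- withr::local_tempdir()
  export_indicators(r, dir)
  phi <- read_indicators(dir)$phi
  expect_equal(phi$phi[phi$rep == "mean" & phi$k == 50], 1)
})

test_that("isochrone band export partitions the grid", {
  g <- make_line_grid(10)
  f <- shortest_time_field(g, c(0, 0))
  geo <- export_isochrone_bands(f, c(5, 10))
  sizes <- vapply(geo$features, function(ft) ft$properties$n_cells, numeric(1))
  # cells at 0..5 min, at 6..9 min, and nothing beyond
  expect_equal(sizes, c(6, 4, 0))
  expect_equal(sum(sizes), length(f$minutes))
  # every cell appears in exactly one band
  n_rings <- sum(vapply(geo$features, function(ft)
    length(ft$geometry$coordinates), numeric(1)))
  expect_equal(n_rings, length(f$minutes))

  # a uniform 55-minute field lands entirely in the (50,60] band
  u <- emscover:::new_field(rep(55, g$n_cells), g, kind = "rescue")
  geo2 <- export_isochrone_bands(u, seq(10, 60, 10))
  nz <- which(vapply(geo2$features, function(ft) ft$properties$n_cells,
                     numeric(1)) > 0)
  expect_equal(geo2$features[[nz]]$properties$band, "(50,60]")

  # the capital's cell falls in the first band of the bundled scenario
  sc <- make_avila_scenario()
  st <- static_indicators(sc)
  geo3 <- export_isochrone_bands(st$field, sc$thresholds,
                                 cell_size = sc$cell_size)
  cap <- sc$towns[sc$towns$town == "Avila", ]
  first_band <- geo3$features[[1]]$geometry$coordinates
  corners <- vapply(first_band, function(ring) ring[[1]][[1]], numeric(2))
  expect_true(any(corners[1, ] == cap$col & corners[2, ] == cap$row))

  # writing to disk produces valid JSON with the same structure
  path <- withr::local_tempfile(fileext = ".geojson")
  export_isochrone_bands(f, c(5, 10), path = path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, 3)
  expect_error(export_isochrone_bands(f, c(10, 5)), class = "ems_validation_error")
})
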