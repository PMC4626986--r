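test_that("dynamic rescue field: free units give the static field, busy units add their wait", {
  g <- make_line_grid(10)
  hub <- cell_id_at(g, 0, 0)
  static <- shortest_time_field(g, c(0, 0))
  free_amb <- tibble::tibble(cell = hub, free = TRUE, avail_time = 0,
                             avail_cell = hub)
  f <- dynamic_rescue_field(g, free_amb, now = 0)
  expect_equal(f$minutes, static$minutes)
  # one busy unit freeing at the hub in 12 minutes: static field + 12
  busy <- tibble::tibble(cell = cell_id_at(g, 0, 7), free = FALSE,
                         avail_time = 112, avail_cell = hub)
  fb <- dynamic_rescue_field(g, busy, now = 100)
  expect_equal(fb$minutes[g$road], static$minutes[g$road] + 12)
  # with a second, free unit the cellwise minimum wins
  two <- rbind(busy, free_amb)
  f2 <- dynamic_rescue_field(g, two, now = 100)
  expect_equal(f2$minutes[g$road], pmin(static$minutes[g$road] + 12,
                                        static$minutes[g$road]))
  # the dynamic field never beats the static field
  expect_true(all(fb$minutes[g$road] >= static$minutes[g$road]))
  # literal busy penalty variant: travel from current position to the
  # availability cell (7 min) instead of the remaining 12
  fl <- dynamic_rescue_field(g, busy, now = 100,
                             busy_penalty = "travel_to_availability")
  expect_equal(fl$minutes[g$road], static$minutes[g$road] + 7)
})

test_that("phi_k is the covered population share, monotone and bounded", {
  sc <- make_avila_scenario()
  st <- static_indicators(sc)
  expect_equal(round(100 * st$phi$phi[st$phi$k == 10]), 75)
  expect_equal(st$phi$phi[st$phi$k == 50], 1)
  expect_true(all(diff(st$phi$phi) >= 0))
  expect_true(all(st$phi$phi >= 0 & st$phi$phi <= 1))
  # a field with no reachable cell covers nobody
  g <- sc$grid
  allinf <- emscover:::new_field(rep(Inf, g$n_cells), g, kind = "rescue")
  pop <- tibble::tibble(cell = sc$towns$cell, population = sc$towns$population)
  expect_equal(phi_k(allinf, pop, c(10, 60)), c(0, 0))
  # zero total population is undefined
  expect_error(phi_k(st$field, tibble::tibble(cell = g$hub, population = 0), 10),
               class = "ems_validation_error")
})

test_that("pi_k: static town coverage is 0/1 by band; time-split cases average exactly", {
  sc <- make_avila_scenario()
  st <- static_indicators(sc)
  cap <- st$town_pi[st$town_pi$town == "Avila", ]
  expect_equal(cap$pi, rep(1, 6))
  nav <- st$town_pi[st$town_pi$town == "Navaluenga", ]
  expect_equal(nav$pi[nav$k == 30], 0)
  expect_equal(nav$pi[nav$k == 40], 1)
  expect_true(all(diff(nav$pi[order(nav$k)]) >= 0))
  # covered exactly half of the frame
  tl <- tibble::tibble(time = c(0, 50), rescue = c(5, 100))
  expect_equal(pi_k(tl, 10, timeframe = c(0, 100)), 0.5)
  expect_equal(pi_k(tl, 200, timeframe = c(0, 100)), 1)
})

test_that("occupation partitions each unit's horizon into the four stages", {
  # scripted log with all four stages in equal quarters
  iv <- tibble::tibble(unit = 1L,
                       stage = c("prep", "to_scene", "on_scene", "free"),
                       start = c(0, 25, 50, 75), end = c(25, 50, 75, 100))
  occ <- occupation(iv, 100)
  expect_equal(occ$fraction, rep(0.25, 4))
  expect_equal(sort(unique(occ$stage)),
               c("assistance", "free", "preparation", "travelling"))
  # gap in the log violates conservation
  bad <- iv; bad$start[2] <- 30
  expect_error(occupation(bad, 100), class = "ems_conservation_error")
  # random tilings always sum to one
  for (seed in 1:5) {
    cuts <- emscover:::with_seed(seed, sort(stats::runif(7, 0, 100)))
    b <- c(0, cuts, 100)
    stages <- emscover:::with_seed(seed + 50,
      sample(c("prep", "to_scene", "on_scene", "to_hospital", "at_hospital",
               "returning", "free"), 8, replace = TRUE))
    ivr <- tibble::tibble(unit = 1L, stage = stages,
                          start = b[-9], end = b[-1])
    expect_equal(sum(occupation(ivr, 100)$fraction), 1, tolerance = 1e-12)
  }
})

test_that("time averages are exact for piecewise-constant timelines and chain over subframes", {
  # constant timeline
  expect_equal(unname(time_average(tibble::tibble(time = 0, v = 3), c(0, 10))), 3)
  # two halves
  tl <- tibble::tibble(time = c(0, 5), v = c(2, 6))
  expect_equal(unname(time_average(tl, c(0, 10))), 4)
  expect_error(time_average(tl[0, ], c(0, 10)), class = "ems_validation_error")
  # random piecewise-constant timelines match a Riemann-sum oracle
  for (seed in 1:8) {
    tms <- emscover:::with_seed(seed, c(0, sort(stats::runif(9, 0, 100))))
    vls <- emscover:::with_seed(seed + 9, stats::rnorm(10))
    tl <- tibble::tibble(time = tms, v = vls)
    expect_equal(unname(time_average(tl, c(0, 100))),
                 riemann_average(tms, vls, 0, 100), tolerance = 1e-3)
    # chaining: averages over [0,30) and [30,100) recombine exactly
    a1 <- unname(time_average(tl, c(0, 30)))
    a2 <- unname(time_average(tl, c(30, 100)))
    expect_equal((30 * a1 + 70 * a2) / 100, unname(time_average(tl, c(0, 100))),
                 tolerance = 1e-12)
  }
})

test_that("availability sits beside coverage across staffing levels", {
  sc <- make_random_scenario(12, horizon_days = 10)
  r1 <- replicate_ems(sc, replications = 2, seed = 5, ambulances = 1)
  tab1 <- availability_vs_coverage(list(r1))
  expect_equal(unique(tab1$c), 1L)
  expect_equal(nrow(tab1), length(sc$thresholds))
  r2 <- replicate_ems(sc, replications = 2, seed = 5, ambulances = 2)
  tab <- availability_vs_coverage(list(r1, r2))
  av <- unique(tab[c("c", "availability")])
  expect_true(av$availability[av$c == 2] >= av$availability[av$c == 1] - 1e-9)
  # without accidents availability is 1 for any c
  q <- quiet_avila(horizon_days = 7)
  rq <- simulate_ems(q, seed = 1, rep = 1, ambulances = 2)
  expect_equal(availability_vs_coverage(list(rq))$availability[1], 1)
})
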