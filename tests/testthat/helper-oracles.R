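# Independent oracles and small fixtures used across the suite.

# straight road of n cells on one row; hub (and hospital) at cell 0
make_line_grid <- function(n = 10, minutes = 1) {
  ems_grid(data.frame(row = 0L, col = 0:(n - 1), minutes = minutes,
                      hub = c(TRUE, rep(FALSE, n - 1)),
                      hospital = c(TRUE, rep(FALSE, n - 1))))
}

# random connected grid (<= 6x6) built through the package's own generator,
# but only the grid part is used by the routing oracles
random_small_grid <- function(seed, nrow = 5, ncol = 5, n_cells = 12) {
  make_random_scenario(seed, nrow = nrow, ncol = ncol,
                       n_road_cells = n_cells, n_towns = 1, n_roads = 2)$grid
}

# brute-force shortest-time oracle: exhaustive enumeration of all simple
# paths over the road graph, edge cost (w[u] + w[v]) / 2
brute_force_times <- function(grid, source_id, w = grid$minutes) {
  best <- rep(Inf, grid$n_cells)
  best[source_id] <- 0
  visit <- function(u, cost, seen) {
    for (v in grid$adj[[u]]) {
      if (seen[v]) next
      nc <- cost + (w[u] + w[v]) / 2
      if (nc < best[v]) best[v] <<- nc
      seen2 <- seen; seen2[v] <- TRUE
      visit(v, nc, seen2)
    }
  }
  seen <- logical(grid$n_cells)
  seen[source_id] <- TRUE
  visit(source_id, 0, seen)
  best
}

# Riemann-sum oracle for time averages of piecewise-constant signals
riemann_average <- function(times, values, from, to, dt = 1e-3) {
  grid_t <- seq(from, to - dt / 2, by = dt)
  idx <- findInterval(grid_t, times)
  mean(values[idx])
}

# scenario with no accidents, weather, festivities or hotel dynamics
quiet_avila <- function(horizon_days = 14, ...) {
  sc <- make_avila_scenario(horizon_days = horizon_days, ...)
  sc$accident_rates$lambda <- 0
  sc$weather_days$days <- 0
  sc$festivity_days$days <- 0
  sc$calendar <- emscover:::build_calendar(sc)
  sc
}

no_overlays <- function() penalty_overlay("rain", 2, 0, 1)[0, ]

no_accidents <- function() {
  tibble::tibble(id = integer(), time = numeric(), cell = integer(),
                 road = character(), prep = numeric(), on_scene = numeric(),
                 at_hospital = numeric())
}

scripted_accident <- function(time, cell, prep = 10, on_scene = 30,
                              at_hospital = 15, id = 1L, road = "R1") {
  tibble::tibble(id = id, time = time, cell = cell, road = road,
                 prep = prep, on_scene = on_scene, at_hospital = at_hospital)
}

cell_id_at <- function(grid, row, col) emscover:::cell_index(row, col, grid$ncol)
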