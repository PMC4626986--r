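#' Generate a random small scenario
#'
#' Builds a random but always-valid scenario for property testing: a random
#' connected road tree grown from a hub on a small grid, random per-cell
#' traversal minutes, random towns, accident rates, weather and festivity
#' tables. Deterministic for a fixed seed.
#'
#' @param seed Seed controlling the whole construction.
#' @param nrow,ncol Grid dimensions (>= 3).
#' @param n_road_cells Number of road cells to grow (including the hub).
#' @param n_towns Number of towns (placed on road cells).
#' @param n_roads Number of rated road segments.
#' @param horizon_days Scenario horizon (kept short for testing).
#' @param max_lambda Upper bound of the uniform monthly accident means.
#' @param ... Passed on to [ems_scenario()].
#' @return An [ems_scenario()].
#' @export
make_random_scenario <- function(seed, nrow = 8, ncol = 8, n_road_cells = 20,
                                 n_towns = 3, n_roads = 4, horizon_days = 30,
                                 max_lambda = 3, ...) {
  if (nrow < 3 || ncol < 3 || n_road_cells < 4 || n_road_cells > nrow * ncol)
    ems_abort("grid too small for a random scenario", "ems_validation_error")
  with_seed(as.integer(seed), {
    # grow a random connected set of cells from a random start
    start <- c(sample.int(nrow, 1) - 1L, sample.int(ncol, 1) - 1L)
    taken <- matrix(FALSE, nrow, ncol)
    taken[start[1] + 1, start[2] + 1] <- TRUE
    cells <- matrix(start, 1, 2)
    while (nrow(cells) < n_road_cells) {
      i <- sample.int(nrow(cells), 1)
      dirs <- matrix(c(-1, 0, 1, 0, 0, -1, 0, 1), 4, 2, byrow = TRUE)
      cand <- sweep(dirs, 2, cells[i, ], `+`)
      ok <- cand[, 1] >= 0 & cand[, 1] < nrow & cand[, 2] >= 0 & cand[, 2] < ncol
      cand <- cand[ok, , drop = FALSE]
      cand <- cand[!taken[cbind(cand[, 1] + 1, cand[, 2] + 1)], , drop = FALSE]
      if (!nrow(cand)) next
      pick <- cand[sample.int(nrow(cand), 1), ]
      taken[pick[1] + 1, pick[2] + 1] <- TRUE
      cells <- rbind(cells, pick)
    }
    n <- nrow(cells)
    hubi <- 1L
    grid_cells <- tibble::tibble(
      row = cells[, 1], col = cells[, 2],
      minutes = round(stats::runif(n, 1, 4), 2),
      hub = seq_len(n) == hubi,
      hospital = seq_len(n) %in% c(hubi, sample.int(n, 1)))
    grid <- ems_grid(grid_cells, nrow = nrow, ncol = ncol)

    ti <- sample(setdiff(seq_len(n), hubi), min(n_towns, n - 1))
    towns <- tibble::tibble(
      town = paste0("town", seq_along(ti)),
      row = as.integer(cells[ti, 1]), col = as.integer(cells[ti, 2]),
      population = round(stats::runif(length(ti), 100, 5000)))

    seg <- sort(rep_len(seq_len(n_roads), n))
    road_cells <- tibble::tibble(road = paste0("R", seg),
                                 row = cells[, 1], col = cells[, 2])
    rates <- tibble::tibble(road = rep(paste0("R", seq_len(n_roads)), each = 12),
                            month = rep(1:12, n_roads),
                            lambda = round(stats::runif(12 * n_roads, 0, max_lambda), 2))
    weather_events <- tibble::tibble(
      event = c("static", "rain", "snow", "fog", "ice"),
      duration = c(720, 120, 240, 120, 240),
      factor = c(1, 2, 3, 3, 4))
    weather_days <- tibble::tibble(
      event = rep(c("rain", "snow", "fog", "ice"), each = 12),
      month = rep(1:12, 4),
      days = round(stats::runif(48, 0, 4), 1))
    festivity_days <- tibble::tibble(
      type = rep(c("local_events", "roads_closed"), each = 12),
      month = rep(1:12, 2),
      days = sample(0:6, 24, replace = TRUE))
    ems_scenario(
      name = sprintf("random-%d", as.integer(seed)), grid = grid,
      towns = towns, accident_rates = rates, road_cells = road_cells,
      weather_events = weather_events, weather_days = weather_days,
      hotel_stays = round(stats::runif(12, 0, 2000)),
      festivity_days = festivity_days, horizon_days = horizon_days,
      replications = 2, seed = as.integer(seed),
      thresholds = c(5, 10, 20, 30, 45, 60), ...)
  })
}
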