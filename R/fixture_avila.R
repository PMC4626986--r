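# The bundled Avila (Spain) 2014 scenario.
#
# Populations, hotel stays, per-road monthly accident means, festivity days,
# meteorology days and the weather-event catalogue are the published 2014
# figures for the province. The road network is synthetic: real hub-to-town
# travel times for the region are not published, so a radial grid (four
# straight spokes and four staircase spokes, 5 min per cell) reproduces the
# documented travel-time bands instead of the actual road map. Hub and
# hospital are co-located in the capital, which lies within 10 minutes of the
# hub; Navaluenga sits in the (30,40] band and Hoyo de Pinares in (40,50].
# The remaining bands are not documented and are fixture choices: El Tiemblo
# at 15 min, El Barraco at 25 min, Piedrahita at 45 min. The six towns hold
# 90% of the covered population; the remainder lives in four synthetic
# settlements placed 20, 30, 40 and 50 minutes from the hub.

#' Raw input tables of the Avila 2014 scenario
#'
#' The published monthly inputs: per-road mean accident counts, town static
#' populations (persons), province hotel stays (persons/month), festivity and
#' road-closure days, mean weather event-days, and the weather event
#' catalogue (durations and penalty factors).
#'
#' @return A named list of tibbles/vectors: `accident_rates`, `populations`,
#'   `hotel_stays`, `festivity_days`, `weather_days`, `weather_events`.
#' @export
avila_tables <- function() {
  rates_wide <- list(
    "A-50"   = c(3, 3, 3, 2, 6, 1, 4, 2, 3, 0, 1, 3),
    "A-51"   = c(0, 2, 0, 2, 1, 0, 2, 1, 0, 2, 1, 1),
    "A-6"    = c(2, 4, 2, 3, 3, 3, 3, 4, 8, 2, 2, 3),
    "AP-51"  = c(0, 0, 0, 0, 0, 1, 0, 0, 0, 1, 0, 2),
    "AP-6"   = c(3, 0, 2, 2, 0, 1, 1, 1, 2, 1, 1, 1),
    "AV-110" = c(1, 2, 4, 0, 0, 0, 1, 0, 3, 2, 1, 2),
    "AV-500" = c(1, 0, 0, 0, 1, 1, 1, 2, 2, 1, 3, 2),
    "AV-502" = c(0, 4, 5, 2, 0, 1, 3, 7, 1, 1, 1, 0),
    "AV-503" = c(1, 0, 0, 0, 0, 0, 0, 0, 1, 1, 2, 4),
    "AV-804" = c(1, 0, 1, 3, 2, 0, 1, 2, 4, 0, 3, 1),
    "AV-900" = c(4, 1, 1, 0, 0, 0, 3, 2, 2, 2, 1, 2),
    "AV-902" = c(1, 1, 1, 4, 0, 0, 2, 3, 0, 1, 1, 0),
    "CL-501" = c(8, 7, 4, 7, 8, 4, 6, 10, 4, 4, 15, 9),
    "CL-505" = c(2, 4, 4, 2, 1, 0, 4, 3, 4, 2, 6, 1),
    "N-110"  = c(15, 10, 11, 10, 7, 9, 11, 8, 9, 7, 9, 7),
    "N-403"  = c(8, 7, 5, 5, 4, 4, 5, 5, 7, 13, 6, 5),
    "N-501"  = c(0, 1, 0, 0, 1, 0, 3, 1, 0, 1, 1, 3),
    "N-502"  = c(10, 8, 2, 1, 5, 6, 5, 5, 5, 5, 2, 8))
  accident_rates <- tibble::tibble(
    road = rep(names(rates_wide), each = 12),
    month = rep(1:12, times = length(rates_wide)),
    lambda = unlist(rates_wide, use.names = FALSE))
  list(
    accident_rates = accident_rates,
    populations = tibble::tibble(
      town = c("Avila", "El Tiemblo", "Hoyo de Pinares", "Navaluenga",
               "Piedrahita", "El Barraco"),
      population = c(58933, 4000, 2000, 2000, 2000, 2000)),
    hotel_stays = 1000 * c(18, 24, 38, 45, 42, 37, 46, 61, 48, 46, 31, 32),
    festivity_days = tibble::tibble(
      type = rep(c("local_events", "roads_closed"), each = 12),
      month = rep(1:12, 2),
      days = c(0, 4, 0, 1, 10, 12, 1, 6, 19, 11, 0, 0,
               0, 2, 12, 11, 10, 29, 13, 12, 20, 6, 0, 0)),
    weather_days = tibble::tibble(
      event = rep(c("rain", "snow", "storms", "fog", "ice"), each = 12),
      month = rep(1:12, 5),
      days = c(5.9, 5.0, 4.2, 7.8, 9.0, 4.7, 1.9, 2.6, 4.4, 7.6, 7.1, 6.7,
               4.5, 4.3, 2.3, 2.2, 0.4, 0.0, 0.0, 0.0, 0.0, 0.1, 1.9, 3.2,
               4.5, 2.3, 1.5, 1.2, 1.0, 0.6, 0.3, 0.3, 0.7, 1.3, 3.4, 4.1,
               20.1, 16.4, 12.6, 6.6, 1.7, 0.1, 0.0, 0.0, 0.3, 1.7, 11.5, 16.3,
               rep(0, 12))),
    weather_events = tibble::tibble(
      event = c("static", "rain", "snow", "fog", "ice"),
      duration = c(720, 120, 240, 120, 240),
      factor = c(1, 2, 3, 3, 4)))
}

# radial road network: spokes as ordered (row, col) sequences away from the
# hub at (10, 10); cell i of a straight spoke is i cells (5 min each) out
avila_spokes <- function() {
  stair <- function(r0, c0, dr, dc) {
    cells <- matrix(NA_integer_, 10, 2)
    r <- r0; cc <- c0
    for (i in 1:10) {
      cells[i, ] <- c(r, cc)
      if (i %% 2 == 1) r <- r + dr else cc <- cc + dc
    }
    cells
  }
  list(
    N = cbind(9:0, 10), S = cbind(11:20, 10),
    E = cbind(10, 11:20), W = cbind(10, 9:0),
    NE = stair(9, 11, -1, 1), NW = stair(9, 9, -1, -1),
    SE = stair(11, 11, 1, 1), SW = stair(11, 9, 1, -1))
}

#' Build the Avila-like scenario
#'
#' Assembles the bundled Avila 2014 scenario: published input tables on a
#' synthetic radial network reproducing the documented travel-time bands (see
#' the package vignette for the fixture choices). The capital's static share
#' of the population is about 75%, so the static 10-minute coverage is 75%
#' and the 50-minute coverage is 100%.
#'
#' @param ambulances Staffed ambulance count (default 1, the current
#'   deployment).
#' @param path Optional directory: when given, the bundle is also written
#'   there with [write_scenario()].
#' @param ... Further arguments passed to [ems_scenario()] (e.g. `seed`,
#'   `stress_multiplier`, `horizon_days`).
#' @return An [ems_scenario()].
#' @export
make_avila_scenario <- function(ambulances = 1, path = NULL, ...) {
  tab <- avila_tables()
  spokes <- avila_spokes()
  cells <- do.call(rbind, spokes)
  grid_cells <- tibble::tibble(
    row = c(10L, cells[, 1]), col = c(10L, cells[, 2]), minutes = 5,
    hub = c(TRUE, rep(FALSE, nrow(cells))),
    hospital = c(TRUE, rep(FALSE, nrow(cells))))
  grid <- ems_grid(grid_cells, nrow = 21, ncol = 21)

  # towns on documented bands; settlements hold the remaining 10% of the
  # population, outside 10 min and inside 50 min of the hub
  six <- tab$populations
  total <- sum(six$population) / 0.9
  rest <- total - sum(six$population)
  towns <- tibble::tibble(
    town = c(six$town, paste("Settlement", c("A", "B", "C", "D"))),
    row = c(10L, 10L, 5L, 3L, 19L, 10L, 12L, 7L, 14L, 10L),
    col = c(11L, 13L, 14L, 10L, 10L, 5L, 8L, 7L, 14L, 20L),
    population = c(six$population, rest * c(0.3, 0.3, 0.2, 0.2)),
    settlement = rep(c(FALSE, TRUE), c(6L, 4L)))

  # 18 rated roads partition the 80 non-hub road cells into contiguous runs
  runs <- list(
    spokes$N[1:5, ], spokes$N[6:10, ], spokes$S[1:5, ], spokes$S[6:10, ],
    spokes$E[1:5, ], spokes$E[6:10, ], spokes$W[1:5, ], spokes$W[6:10, ],
    spokes$NE[1:4, ], spokes$NE[5:7, ], spokes$NE[8:10, ],
    spokes$NW[1:4, ], spokes$NW[5:7, ], spokes$NW[8:10, ],
    spokes$SE[1:5, ], spokes$SE[6:10, ], spokes$SW[1:5, ], spokes$SW[6:10, ])
  roads <- unique(tab$accident_rates$road)
  road_cells <- dplyr::bind_rows(lapply(seq_along(roads), function(i)
    tibble::tibble(road = roads[i], row = runs[[i]][, 1], col = runs[[i]][, 2])))

  sc <- ems_scenario(
    name = "avila-2014", grid = grid, towns = towns,
    accident_rates = tab$accident_rates, road_cells = road_cells,
    weather_events = tab$weather_events, weather_days = tab$weather_days,
    hotel_stays = tab$hotel_stays, festivity_days = tab$festivity_days,
    ambulances = ambulances, ...)
  if (!is.null(path)) write_scenario(sc, path)
  sc
}
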