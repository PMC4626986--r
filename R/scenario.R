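#' Assemble and validate a simulation scenario
#'
#' A scenario bundles everything one run of the simulator needs: the road
#' grid, the towns with their static populations, per-road monthly mean
#' accident counts, the weather event catalogue and monthly event-day counts,
#' monthly festivity/road-closure day counts, service-time distributions and
#' the run controls (horizon, replications, number of ambulances, isochrone
#' thresholds, stress multiplier, seed).
#'
#' @param name Scenario name.
#' @param grid An [ems_grid()].
#' @param towns Tibble with columns `town`, `row`, `col`, `population`
#'   (persons, > 0) and optionally `settlement` (logical; small settlements
#'   that share the hotel-stay split but are not headline towns).
#' @param accident_rates Tibble `road`, `month` (1-12), `lambda` (mean
#'   accidents per month, >= 0).
#' @param road_cells Tibble `road`, `row`, `col`: the cells making up each
#'   rated road segment (>= 1 cell per road).
#' @param weather_events Tibble `event`, `duration` (minutes), `factor`
#'   (>= 1); the `static` row must have factor 1.
#' @param weather_days Tibble `event`, `month`, `days` (mean event-days, >= 0).
#' @param hotel_stays Numeric length-12 vector of monthly province hotel
#'   stays (persons), split over towns proportional to population.
#' @param festivity_days Tibble `type` (`"local_events"` or `"roads_closed"`),
#'   `month`, `days` (integer counts).
#' @param service_times List with `prep = c(meanlog, sdlog)` (lognormal,
#'   log-scale parameters), `on_scene = c(min, max)` (uniform) and
#'   `at_hospital = c(min, mode, max)` (triangular), all in minutes.
#' @param horizon_days Simulated horizon in days (default 365).
#' @param replications Default replication count (default 20).
#' @param ambulances Number of ambulances staffed at the hub, `c >= 1`.
#' @param thresholds Ascending isochrone thresholds K in minutes; the 60-min
#'   level is the Golden Hour.
#' @param stress_multiplier Multiplies every task time and travel time
#'   (sensitivity/stress runs use 2).
#' @param seed Default master seed for runs of this scenario.
#' @param year Calendar year supplying month lengths and weekends.
#' @param congestion_extra_min Minutes a congestion overlay outlives the
#'   serving ambulance's departure from the scene (default 60).
#' @param weekend_uplift Floating-population factor applied on weekends and
#'   local-event days (default 1.2, i.e. +20%).
#' @param congestion_factor,festivity_factor Doubling factors for accident
#'   congestion and road-closure days.
#' @param required_units Ambulances required per accident (default 1).
#' @param dispatch_from_hospital If `TRUE`, a unit may take a new call right
#'   after the hospital drop-off instead of only after returning to the hub.
#' @param storm_as Optional weather event name to which "storm" days are
#'   mapped; storms have no penalty factor of their own and are ignored by
#'   default.
#' @param cell_size Abstract cell edge length used when exporting GeoJSON.
#' @return An object of class `ems_scenario`.
#' @export
ems_scenario <- function(name, grid, towns, accident_rates, road_cells,
                         weather_events, weather_days, hotel_stays,
                         festivity_days, service_times = default_service_times(),
                         horizon_days = 365, replications = 20, ambulances = 1,
                         thresholds = c(10, 20, 30, 40, 50, 60),
                         stress_multiplier = 1, seed = 1L, year = 2014,
                         congestion_extra_min = 60, weekend_uplift = 1.2,
                         congestion_factor = 2, festivity_factor = 2,
                         required_units = 1, dispatch_from_hospital = FALSE,
                         storm_as = NULL, cell_size = 1) {
  towns <- tibble::as_tibble(towns)
  if (!"settlement" %in% names(towns)) towns$settlement <- FALSE
  towns$settlement <- as.logical(towns$settlement)
  towns$cell <- cell_index(towns$row, towns$col, grid$ncol)
  sc <- structure(list(
    name = name, grid = grid, towns = towns,
    accident_rates = tibble::as_tibble(accident_rates),
    road_cells = tibble::as_tibble(road_cells),
    weather_events = tibble::as_tibble(weather_events),
    weather_days = tibble::as_tibble(weather_days),
    hotel_stays = as.numeric(hotel_stays),
    festivity_days = tibble::as_tibble(festivity_days),
    service_times = service_times,
    horizon_days = as.numeric(horizon_days),
    replications = as.integer(replications),
    ambulances = as.integer(ambulances),
    thresholds = as.numeric(thresholds),
    stress_multiplier = as.numeric(stress_multiplier),
    seed = as.integer(seed), year = as.integer(year),
    congestion_extra_min = as.numeric(congestion_extra_min),
    weekend_uplift = as.numeric(weekend_uplift),
    congestion_factor = as.numeric(congestion_factor),
    festivity_factor = as.numeric(festivity_factor),
    required_units = as.integer(required_units),
    dispatch_from_hospital = isTRUE(dispatch_from_hospital),
    storm_as = storm_as, cell_size = as.numeric(cell_size)
  ), class = "ems_scenario")
  sc$calendar <- build_calendar(sc)
  validate_scenario(sc)
  sc
}

#' Default ambulance service-time distributions
#'
#' Preparation at the hub is lognormal with log-scale parameters (2.5, 1)
#' minutes (median about 12.2 min); time at the accident site is uniform on
#' (23.2, 37.2) min; time at the hospital is triangular with
#' (min, mode, max) = (12.7, 13.7, 21.9) min.
#' @return A list understood by [ems_scenario()].
#' @export
default_service_times <- function() {
  list(prep = c(meanlog = 2.5, sdlog = 1),
       on_scene = c(min = 23.2, max = 37.2),
       at_hospital = c(min = 12.7, mode = 13.7, max = 21.9))
}

validate_scenario <- function(sc) {
  bad <- function(msg) ems_abort(msg, "ems_validation_error")
  if (sc$ambulances < 1) bad("ambulance count c must be >= 1")
  if (sc$replications < 1) bad("replications must be >= 1")
  if (sc$stress_multiplier <= 0) bad("stress_multiplier must be > 0")
  if (sc$required_units < 1) bad("required_units must be >= 1")
  K <- sc$thresholds
  if (length(K) == 0 || any(K <= 0) || any(diff(K) <= 0))
    bad("thresholds K must be strictly ascending and > 0")
  if (nrow(sc$towns) == 0) bad("scenario needs at least one town")
  if (any(sc$towns$population <= 0)) bad("town populations must be > 0")
  if (anyDuplicated(sc$towns$town)) bad("duplicated town names")
  off_grid <- !sc$towns$cell %in% which(sc$grid$road)
  if (any(off_grid))
    bad(paste("town cells not on the road network:",
              paste(sc$towns$town[off_grid], collapse = ", ")))
  if (length(sc$hotel_stays) != 12 || any(sc$hotel_stays < 0))
    bad("hotel_stays must be 12 non-negative monthly values")

  ar <- sc$accident_rates
  if (nrow(ar)) {
    if (!all(c("road", "month", "lambda") %in% names(ar)))
      bad("accident_rates needs columns road, month, lambda")
    neg <- ar$lambda < 0
    if (any(neg))
      bad(paste("negative accident rates for:",
                paste(unique(paste0(ar$road[neg], "/", MONTHS3[ar$month[neg]])),
                      collapse = ", ")))
    segs <- unique(ar$road)
    missing_cells <- setdiff(segs, unique(sc$road_cells$road))
    if (length(missing_cells))
      bad(paste("rated roads without cells:", paste(missing_cells, collapse = ", ")))
    rcid <- cell_index(sc$road_cells$row, sc$road_cells$col, sc$grid$ncol)
    if (!all(sc$grid$road[rcid]))
      bad("road segment cells must be road cells of the grid")
  }

  we <- sc$weather_events
  if (!all(c("event", "duration", "factor") %in% names(we)))
    bad("weather_events needs columns event, duration, factor")
  low <- we$factor < 1
  if (any(low))
    bad(paste("weather penalty factors below 1 for:",
              paste(we$event[low], collapse = ", ")))
  if ("static" %in% we$event && any(we$factor[we$event == "static"] != 1))
    bad("the static weather row must have penalty factor 1")
  if (any(we$duration <= 0)) bad("weather event durations must be > 0")
  wd <- sc$weather_days
  if (nrow(wd) && any(wd$days < 0)) bad("mean weather event-days must be >= 0")

  st <- sc$service_times
  if (st$on_scene[["min"]] >= st$on_scene[["max"]])
    bad("on-scene uniform bounds must satisfy min < max")
  tri <- st$at_hospital
  if (!(tri[["min"]] <= tri[["mode"]] && tri[["mode"]] <= tri[["max"]]))
    bad("hospital triangular parameters must satisfy min <= mode <= max")
  invisible(sc)
}

#' @export
print.ems_scenario <- function(x, ...) {
  cat(sprintf(paste0("<ems_scenario> %s: %d towns (+%d settlements), %d rated roads,\n",
                     "  c = %d ambulance(s), horizon %g days, K = {%s}, stress %g, seed %d\n"),
              x$name, sum(!x$towns$settlement), sum(x$towns$settlement),
              length(unique(x$accident_rates$road)), x$ambulances,
              x$horizon_days, paste(x$thresholds, collapse = ","),
              x$stress_multiplier, x$seed))
  invisible(x)
}

# Per-day calendar over the horizon: month, weekend, local-event and
# road-closure flags. Monthly festivity day counts are placed on
# deterministic, evenly spaced days of the month.
build_calendar <- function(sc) {
  n <- ceiling(sc$horizon_days)
  dates <- seq(as.Date(sprintf("%d-01-01", sc$year)), by = "day", length.out = n)
  month <- as.integer(format(dates, "%m"))
  ymon <- format(dates, "%Y-%m")
  wday <- as.integer(format(dates, "%u"))
  cal <- tibble::tibble(day = seq_len(n), date = dates, month = month,
                        weekend = wday >= 6, holiday = FALSE, closed = FALSE)
  fd <- sc$festivity_days
  for (ym in unique(ymon)) {
    idx <- which(ymon == ym)
    m <- month[idx[1]]
    for (type in c("local_events", "roads_closed")) {
      k <- fd$days[fd$type == type & fd$month == m]
      k <- if (length(k)) min(as.integer(k[1]), length(idx)) else 0L
      if (k > 0L) {
        at <- idx[unique(round(seq(1, length(idx), length.out = k)))]
        if (type == "local_events") cal$holiday[at] <- TRUE else cal$closed[at] <- TRUE
      }
    }
  }
  cal
}

# month spans over the horizon in simulated minutes:
# tibble(month (1-12), start, end)
month_spans <- function(sc) {
  cal <- sc$calendar
  grp <- cumsum(c(TRUE, diff(cal$month) != 0))
  starts <- tapply(cal$day, grp, min)
  ends <- tapply(cal$day, grp, max)
  tibble::tibble(month = cal$month[match(unique(grp), grp)],
                 start = (as.numeric(starts) - 1) * 1440,
                 end = pmin(as.numeric(ends) * 1440, sc$horizon_days * 1440))
}

#' Effective town populations on a given day
#'
#' On weekdays without local events each town holds its static population. On
#' weekends and local-event days the month's hotel stays are first split over
#' towns proportionally to static population, then spread uniformly over that
#' month's weekend + event days, and the resulting population is raised by
#' the floating-population uplift (default +20%).
#'
#' @param scenario An [ems_scenario()].
#' @param day Day of the simulation, 1-based; must lie within the horizon.
#' @return A tibble `town`, `cell`, `population` with the total population as
#'   attribute `"total"`.
#' @export
population_at <- function(scenario, day) {
  cal <- scenario$calendar
  if (day < 1 || day > nrow(cal))
    ems_abort("day outside the simulated horizon", "ems_validation_error")
  d <- cal[day, ]
  tw <- scenario$towns
  pop <- tw$population
  if (d$weekend || d$holiday) {
    m <- d$month
    mdays <- cal[cal$month == m & format(cal$date, "%Y") == format(d$date, "%Y"), ]
    n_boost <- sum(mdays$weekend | mdays$holiday)
    share <- pop / sum(pop)
    spread <- if (n_boost > 0) scenario$hotel_stays[m] * share / n_boost else 0
    pop <- (pop + spread) * scenario$weekend_uplift
  }
  out <- tibble::tibble(town = tw$town, cell = tw$cell, population = pop)
  attr(out, "total") <- sum(pop)
  out
}

# populations for all days at once: matrix horizon_days x towns (persons)
population_matrix <- function(sc) {
  n <- nrow(sc$calendar)
  m <- matrix(0, n, nrow(sc$towns), dimnames = list(NULL, sc$towns$town))
  for (d in seq_len(n)) m[d, ] <- population_at(sc, d)$population
  m
}
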