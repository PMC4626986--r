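# Seeded random generators calibrated to the scenario tables.
#
# Each replication draws from four named substreams (accidents, weather,
# service, population) whose seeds derive from the master seed, so that runs
# with the same (master seed, replication) see identical accident calendars,
# weather calendars and service times regardless of how many ambulances are
# staffed: the common-random-numbers contract behind deployment comparisons.

#' Next accident inter-arrival time on a road segment
#'
#' Accidents on a segment during a month form a Poisson process whose mean
#' monthly count is the segment's rate table entry, so inter-arrival times
#' are exponential with rate `lambda / month_minutes`. A zero rate yields
#' `Inf` (no accident ever).
#'
#' @param lambda Mean accidents per month (>= 0).
#' @param month_minutes Length of the month in minutes.
#' @return Minutes until the next accident (a single random draw).
#' @export
next_accident_time <- function(lambda, month_minutes) {
  if (lambda < 0) ems_abort("lambda must be >= 0", "ems_validation_error")
  if (lambda == 0) return(Inf)
  stats::rexp(1, rate = lambda / month_minutes)
}

# Full accident calendar for one replication. Uses the accidents substream
# for arrival times and accident cells, and the service substream for the
# pre-drawn per-accident service-time triples (so triples attach to accidents
# in occurrence order regardless of the number of ambulances).
sample_accident_calendar <- function(sc, master = sc$seed, rep = 0L,
                                     stress = sc$stress_multiplier) {
  ar <- sc$accident_rates
  spans <- month_spans(sc)
  seg_cells <- split(cell_index(sc$road_cells$row, sc$road_cells$col, sc$grid$ncol),
                     sc$road_cells$road)
  roads <- sort(unique(ar$road))
  acc <- with_seed(substream_seed(master, "accidents", rep), {
    out <- list()
    for (road in roads) {
      cells <- seg_cells[[road]]
      for (i in seq_len(nrow(spans))) {
        lam <- ar$lambda[ar$road == road & ar$month == spans$month[i]]
        lam <- if (length(lam)) lam[1] else 0
        if (lam <= 0) next
        # per-minute rate such that a full month's count is Poisson(lambda)
        t <- spans$start[i]
        rate <- lam / (1440 * days_in_month(sc$year, spans$month[i]))
        repeat {
          t <- t + stats::rexp(1, rate)
          if (t >= spans$end[i]) break
          cell <- if (length(cells) == 1) cells else cells[sample.int(length(cells), 1)]
          out[[length(out) + 1L]] <- c(t, cell)
        }
      }
    }
    out
  })
  if (!length(acc)) {
    return(tibble::tibble(id = integer(), time = numeric(), cell = integer(),
                          road = character(), prep = numeric(),
                          on_scene = numeric(), at_hospital = numeric()))
  }
  m <- do.call(rbind, acc)
  ord <- order(m[, 1])
  times <- m[ord, 1]; cells <- as.integer(m[ord, 2])
  cell2road <- stats::setNames(sc$road_cells$road,
                               cell_index(sc$road_cells$row, sc$road_cells$col,
                                          sc$grid$ncol))
  st <- sample_service_times(sc$service_times, stress = stress,
                             n = length(times),
                             seed = substream_seed(master, "service", rep))
  tibble::tibble(id = seq_along(times), time = times, cell = cells,
                 road = unname(cell2road[as.character(cells)]),
                 prep = st$prep, on_scene = st$on_scene,
                 at_hospital = st$at_hospital)
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  as.integer(seq(first, by = "month", length.out = 2)[2] - first)
}

#' Sample ambulance service times
#'
#' Draws `n` independent triples (preparation, on-scene, at-hospital) minutes
#' from the scenario's lognormal / uniform / triangular distributions; the
#' stress multiplier scales every draw.
#'
#' @param spec Service-time spec, see [default_service_times()].
#' @param stress Multiplier applied to each draw (default 1).
#' @param n Number of triples.
#' @param seed Optional seed; when given, draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @return Tibble `prep`, `on_scene`, `at_hospital`.
#' @export
sample_service_times <- function(spec = default_service_times(), stress = 1,
                                 n = 1, seed = NULL) {
  draw <- function() {
    tibble::tibble(
      prep = stats::rlnorm(n, spec$prep[["meanlog"]], spec$prep[["sdlog"]]) * stress,
      on_scene = stats::runif(n, spec$on_scene[["min"]], spec$on_scene[["max"]]) * stress,
      at_hospital = rtriangular(n, spec$at_hospital[["min"]],
                                spec$at_hospital[["mode"]],
                                spec$at_hospital[["max"]]) * stress)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# inverse-CDF triangular sampler
rtriangular <- function(n, min, mode, max) {
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Sample a weather calendar
#'
#' For every month in the horizon and every penalising event type, the number
#' of events is Poisson with mean equal to the table's monthly event-day
#' count (one recorded event-day corresponds to one event of the catalogued
#' duration). Each event starts uniformly within the month, lasts its
#' catalogued duration and applies its penalty factor to the whole road
#' network (the model carries no spatial weather structure).
#'
#' @param scenario An [ems_scenario()].
#' @param master Master seed (defaults to the scenario seed).
#' @param rep Replication index used to derive the substream seed.
#' @return An overlay table (rows as from [penalty_overlay()]).
#' @export
sample_weather_calendar <- function(scenario, master = scenario$seed, rep = 0L) {
  sc <- scenario
  spans <- month_spans(sc)
  events <- sc$weather_events[sc$weather_events$event %in% WEATHER_CAUSES, ]
  wd <- sc$weather_days
  if (!is.null(sc$storm_as) && "storms" %in% wd$event) {
    st <- wd[wd$event == "storms", ]
    st$event <- sc$storm_as
    wd <- rbind(wd[wd$event != "storms", ], st)
    wd <- dplyr::summarise(dplyr::group_by(wd, .data$event, .data$month),
                           days = sum(.data$days), .groups = "drop")
  }
  with_seed(substream_seed(master, "weather", rep), {
    rows <- list()
    for (ev in sort(events$event)) {
      dur <- events$duration[events$event == ev]
      fac <- events$factor[events$event == ev]
      for (i in seq_len(nrow(spans))) {
        mu <- wd$days[wd$event == ev & wd$month == spans$month[i]]
        mu <- if (length(mu)) mu[1] else 0
        k <- if (mu > 0) stats::rpois(1, mu) else 0L
        if (k > 0) {
          starts <- sort(stats::runif(k, spans$start[i], spans$end[i]))
          for (s in starts)
            rows[[length(rows) + 1L]] <- penalty_overlay(ev, fac, s, s + dur)
        }
      }
    }
    if (length(rows)) dplyr::bind_rows(rows)
    else penalty_overlay("rain", 2, 0, 1)[0, ]
  })
}

# festivity overlays: whole-network doubling on road-closure days
festivity_overlays <- function(sc) {
  days <- which(sc$calendar$closed)
  if (!length(days)) return(penalty_overlay("rain", 2, 0, 1)[0, ])
  dplyr::bind_rows(lapply(days, function(d)
    penalty_overlay("festivity", sc$festivity_factor, (d - 1) * 1440, d * 1440)))
}
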