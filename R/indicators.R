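#' Dynamic rescue-time field
#'
#' The rescue time of a cell at an instant is the travel time from the first
#' available ambulance: for a free unit, the travel time from its current
#' cell; for a busy unit, the remaining time until it becomes available plus
#' the travel time from the cell where it will become available. The field is
#' the cellwise minimum over all units. With every unit free at the hub it
#' reduces to the static hub field.
#'
#' @param grid An [ems_grid()].
#' @param ambulances Tibble with one row per unit: `cell` (current cell id),
#'   `free` (logical), `avail_time` (simulated minute at which a busy unit
#'   becomes available), `avail_cell` (cell id where it becomes available).
#' @param now Evaluation instant (simulated minutes).
#' @param overlays,stress Passed to [shortest_time_field()].
#' @param busy_penalty `"remaining_time"` (default): a busy unit contributes
#'   its remaining unavailability; `"travel_to_availability"`: the literal
#'   travel time from the unit's current position to its availability cell is
#'   used as the penalty instead.
#' @return An `ems_field` of kind `"rescue"`.
#' @export
dynamic_rescue_field <- function(grid, ambulances, now = 0, overlays = NULL,
                                 stress = 1,
                                 busy_penalty = c("remaining_time",
                                                  "travel_to_availability")) {
  busy_penalty <- match.arg(busy_penalty)
  amb <- tibble::as_tibble(ambulances)
  if (nrow(amb) == 0) ems_abort("at least one ambulance required",
                                "ems_validation_error")
  w <- effective_minutes(grid, now, overlays, stress)
  best <- rep(Inf, grid$n_cells)
  for (i in seq_len(nrow(amb))) {
    if (amb$free[i]) {
      f <- dijkstra_field(grid, amb$cell[i], w)
    } else {
      pen <- if (busy_penalty == "remaining_time") {
        max(0, amb$avail_time[i] - now)
      } else {
        d <- dijkstra_field(grid, amb$cell[i], w)
        d[amb$avail_cell[i]]
      }
      f <- pen + dijkstra_field(grid, amb$avail_cell[i], w)
    }
    best <- pmin(best, f)
  }
  new_field(best, grid, kind = "rescue", at = now)
}

#' Population coverage within an isochrone
#'
#' The share of the population lying in cells whose rescue time is at most
#' `k` minutes.
#'
#' @param field An `ems_field` (rescue or travel times, minutes per cell).
#' @param population Tibble `cell`, `population` (persons per population
#'   cell), e.g. from [population_at()].
#' @param k Threshold in minutes (scalar or vector).
#' @return `phi_k` as a fraction in `[0, 1]`, one value per `k`.
#' @export
phi_k <- function(field, population, k) {
  total <- sum(population$population)
  if (!isTRUE(total > 0))
    ems_abort("total population must be > 0", "ems_validation_error")
  rt <- field$minutes[population$cell]
  vapply(k, function(kk) sum(population$population[rt <= kk]) / total,
         numeric(1))
}

#' Coverage curve over all thresholds
#'
#' @inheritParams phi_k
#' @param thresholds Ascending isochrone levels K in minutes.
#' @return An `ems_coverage` tibble with columns `k` and `phi`
#'   (non-decreasing in `k`).
#' @export
coverage_curve <- function(field, population, thresholds) {
  out <- tibble::tibble(k = as.numeric(thresholds),
                        phi = phi_k(field, population, thresholds))
  class(out) <- c("ems_coverage", class(out))
  out
}

#' Time coverage of a town
#'
#' The fraction of a timeframe during which a town's rescue time is within
#' `k` minutes. The timeline is piecewise constant: `rescue[i]` holds from
#' `time[i]` until `time[i+1]` (the last value holds to the end of the
#' frame).
#'
#' @param timeline Tibble `time`, `rescue`: the town cell's rescue time in
#'   minutes, piecewise constant from each `time` on.
#' @param k Threshold minutes (scalar or vector).
#' @param timeframe `c(from, to)` in simulated minutes; defaults to the span
#'   of the timeline.
#' @return `pi_k` fraction(s) in `[0, 1]`.
#' @export
pi_k <- function(timeline, k, timeframe = range(timeline$time)) {
  if (nrow(timeline) == 0) ems_abort("empty timeline", "ems_validation_error")
  from <- timeframe[1]; to <- timeframe[2]
  if (!(to > from)) ems_abort("timeframe must have positive length",
                              "ems_validation_error")
  vapply(k, function(kk) {
    time_weighted_mean(timeline$time, as.numeric(timeline$rescue <= kk), from, to)
  }, numeric(1))
}

# mean of a piecewise-constant signal over [from, to];
# values[i] holds on [times[i], times[i+1]), last value extends to `to`.
time_weighted_mean <- function(times, values, from, to) {
  if (!length(times)) ems_abort("empty timeline", "ems_validation_error")
  if (times[1] > from)
    ems_abort("timeline does not span the frame", "ems_validation_error")
  brk <- c(times, Inf)
  lo <- pmax(brk[-length(brk)], from)
  hi <- pmin(brk[-1], to)
  wt <- pmax(hi - lo, 0)
  sum(values * wt) / (to - from)
}

#' Time-average a piecewise-constant timeline
#'
#' Time-weighted mean of one or several piecewise-constant value columns over
#' a frame. Splitting a frame into sub-frames and chaining the averages
#' (weighted by sub-frame length) reproduces the whole-frame average.
#'
#' @param timeline Tibble with a `time` column and one or more numeric value
#'   columns, each holding from its `time` to the next.
#' @param frame `c(from, to)` in the timeline's time units.
#' @return Named numeric vector of time-weighted means, one per value column.
#' @export
time_average <- function(timeline, frame = range(timeline$time)) {
  if (nrow(timeline) == 0) ems_abort("empty timeline", "ems_validation_error")
  vals <- setdiff(names(timeline), "time")
  vapply(vals, function(v)
    time_weighted_mean(timeline$time, timeline[[v]], frame[1], frame[2]),
    numeric(1))
}

# Stage taxonomy: six tasks fold into four reported occupation stages.
STAGE4 <- c(prep = "preparation",
            to_scene = "travelling", to_hospital = "travelling",
            returning = "travelling",
            on_scene = "assistance", at_hospital = "assistance",
            free = "free")

#' Ambulance occupation report
#'
#' Partitions each unit's horizon into the four activity stages: travelling
#' (to scene, to hospital, returning), preparation, assistance (at the scene
#' and at the hospital) and free. The intervals of each unit must exactly
#' tile the horizon.
#'
#' @param intervals Tibble `unit`, `stage`, `start`, `end` with stages among
#'   `prep`, `to_scene`, `on_scene`, `to_hospital`, `at_hospital`,
#'   `returning`, `free`.
#' @param horizon Horizon length in minutes.
#' @return An `ems_occupation` tibble `unit`, `stage`, `fraction`; fractions
#'   of each unit sum to 1.
#' @export
occupation <- function(intervals, horizon) {
  iv <- tibble::as_tibble(intervals)
  stopifnot(all(c("unit", "stage", "start", "end") %in% names(iv)))
  if (!all(iv$stage %in% names(STAGE4)))
    ems_abort("unknown stage labels in log", "ems_validation_error")
  out <- list()
  for (u in sort(unique(iv$unit))) {
    ui <- iv[iv$unit == u, ]
    ui <- ui[order(ui$start), ]
    covered <- sum(ui$end - ui$start)
    contiguous <- all(abs(ui$start[-1] - ui$end[-nrow(ui)]) < 1e-6)
    if (!contiguous || abs(covered - horizon) > 1e-6 ||
        abs(ui$start[1]) > 1e-6)
      ems_abort(sprintf("log of unit %s does not tile the horizon", u),
                "ems_conservation_error")
    stage4 <- unname(STAGE4[ui$stage])
    dur <- tapply(ui$end - ui$start, factor(stage4, levels = unique(unname(STAGE4))),
                  sum, default = 0)
    out[[length(out) + 1L]] <- tibble::tibble(
      unit = u, stage = names(dur), fraction = as.numeric(dur) / horizon)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("ems_occupation", class(res))
  res
}

#' Availability against population coverage across staffing levels
#'
#' Side-by-side table of the mean free-time fraction and the mean coverage
#' curve for each simulated number of ambulances, the summary used to choose
#' a staffing level.
#'
#' @param results Named list of `ems_replicates` (or single `ems_sim`)
#'   objects, one per ambulance count.
#' @return Tibble `c`, `availability`, `k`, `phi`.
#' @export
availability_vs_coverage <- function(results) {
  rows <- lapply(results, function(r) {
    g <- glance(r)
    ph <- if (inherits(r, "ems_replicates")) r$phi_mean else r$phi
    tibble::tibble(c = g$ambulances, availability = g$availability,
                   k = ph$k, phi = ph$phi)
  })
  dplyr::bind_rows(rows)
}
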