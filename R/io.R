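# Scenario bundles on disk: one YAML config plus plain CSV tables whose
# headers mirror the printed input tables (monthly columns JAN..DEC), plus a
# grid description CSV with 0-based (row, col) coordinates.

BUNDLE_FILES <- c("config.yml", "grid.csv", "towns.csv", "hotel_stays.csv",
                  "accidents.csv", "road_cells.csv", "weather_events.csv",
                  "meteorology.csv", "festivities.csv")

write_csv_exact <- function(df, path) {
  for (nm in names(df)) if (is.double(df[[nm]])) df[[nm]] <- fmt_num(df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

read_csv_plain <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
}

title_case <- function(x) paste0(toupper(substr(x, 1, 1)), substring(x, 2))

# long (id, month, value) -> wide table with JAN..DEC columns, zero-filled
to_month_table <- function(df, id_col, val_col, out_id) {
  ids <- unique(df[[id_col]])
  m <- matrix(0, length(ids), 12, dimnames = list(NULL, MONTHS3))
  for (i in seq_len(nrow(df)))
    m[match(df[[id_col]][i], ids), df$month[i]] <- df[[val_col]][i]
  out <- data.frame(ids, as.data.frame(m), check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1] <- out_id
  out
}

#' Write a scenario bundle to a directory
#'
#' Writes the YAML config and the CSV input tables (grid, towns, hotel
#' stays, per-road monthly accident means, road-segment cells, weather event
#' catalogue, monthly meteorology days, festivity days). Numbers are written
#' so that [load_scenario()] reproduces the scenario bit-exactly.
#'
#' @param scenario An [ems_scenario()].
#' @param path Directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  sc <- scenario
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(
    name = sc$name, year = sc$year, horizon_days = sc$horizon_days,
    replications = sc$replications, seed = sc$seed,
    ambulances = sc$ambulances, thresholds = sc$thresholds,
    stress_multiplier = sc$stress_multiplier,
    congestion_extra_min = sc$congestion_extra_min,
    weekend_uplift = sc$weekend_uplift,
    congestion_factor = sc$congestion_factor,
    festivity_factor = sc$festivity_factor,
    required_units = sc$required_units,
    dispatch_from_hospital = sc$dispatch_from_hospital,
    storm_as = sc$storm_as, cell_size = sc$cell_size,
    grid_nrow = sc$grid$nrow, grid_ncol = sc$grid$ncol,
    service_times = lapply(sc$service_times, as.list))
  yaml::write_yaml(cfg, file.path(path, "config.yml"))

  g <- sc$grid$cells
  write_csv_exact(tibble::tibble(row = g$row, col = g$col, minutes = g$minutes,
                                 hub = g$hub, hospital = g$hospital),
                  file.path(path, "grid.csv"))
  write_csv_exact(tibble::tibble(Towns = sc$towns$town, Pop = sc$towns$population,
                                 row = sc$towns$row, col = sc$towns$col,
                                 settlement = sc$towns$settlement),
                  file.path(path, "towns.csv"))
  hs <- as.data.frame(as.list(stats::setNames(sc$hotel_stays, MONTHS3)))
  write_csv_exact(hs, file.path(path, "hotel_stays.csv"))

  write_csv_exact(to_month_table(sc$accident_rates, "road", "lambda", "Roads"),
                  file.path(path, "accidents.csv"))
  write_csv_exact(tibble::tibble(Roads = sc$road_cells$road,
                                 row = sc$road_cells$row, col = sc$road_cells$col),
                  file.path(path, "road_cells.csv"))

  we <- sc$weather_events
  wetab <- data.frame(Event = c("Duration (minutes)", "Penalty factor"),
                      stats::setNames(as.data.frame(rbind(we$duration, we$factor)),
                                      title_case(we$event)),
                      check.names = FALSE)
  write_csv_exact(wetab, file.path(path, "weather_events.csv"))

  wd <- sc$weather_days
  wd$event <- title_case(wd$event)
  write_csv_exact(to_month_table(wd, "event", "days", "Days/Month"),
                  file.path(path, "meteorology.csv"))

  fd <- sc$festivity_days
  fd$type <- c(local_events = "Local events",
               roads_closed = "Roads closed")[fd$type]
  write_csv_exact(to_month_table(fd, "type", "days", "Type"),
                  file.path(path, "festivities.csv"))
  invisible(path)
}

#' Load a scenario bundle from a directory
#'
#' Reads the config and CSV tables written by [write_scenario()] (or built
#' by hand in the same layout), and returns a fully validated scenario;
#' missing tables and invalid values (negative accident rates, weather
#' factors below 1, towns off the road network, ...) raise classed errors.
#'
#' @param path Bundle directory.
#' @return An [ems_scenario()].
#' @export
load_scenario <- function(path) {
  missing <- BUNDLE_FILES[!file.exists(file.path(path, BUNDLE_FILES))]
  if (length(missing))
    ems_abort(paste("scenario bundle is missing:", paste(missing, collapse = ", ")),
              "ems_missing_table_error")
  cfg <- yaml::read_yaml(file.path(path, "config.yml"))

  g <- read_csv_plain(file.path(path, "grid.csv"))
  towns <- read_csv_plain(file.path(path, "towns.csv"))
  grid_cells <- tibble::tibble(row = g$row, col = g$col, minutes = g$minutes,
                               hub = g$hub, hospital = g$hospital,
                               town = NA_character_)
  idx <- match(paste(towns$row, towns$col),
               paste(grid_cells$row, grid_cells$col))
  if (anyNA(idx))
    ems_abort(paste("town cells absent from grid:",
                    paste(towns$Towns[is.na(idx)], collapse = ", ")),
              "ems_validation_error")
  grid_cells$town[idx] <- towns$Towns
  grid <- ems_grid(grid_cells, nrow = cfg$grid_nrow, ncol = cfg$grid_ncol)

  hs <- read_csv_plain(file.path(path, "hotel_stays.csv"))
  hotel <- as.numeric(unlist(hs[1, MONTHS3]))

  ar <- read_csv_plain(file.path(path, "accidents.csv"))
  ar <- ar[toupper(ar$Roads) != "TOTAL", ]
  rates <- tidyr::pivot_longer(ar, dplyr::all_of(MONTHS3), names_to = "month",
                               values_to = "lambda")
  rates <- tibble::tibble(road = rates$Roads,
                          month = match(rates$month, MONTHS3),
                          lambda = as.numeric(rates$lambda))
  rc <- read_csv_plain(file.path(path, "road_cells.csv"))
  road_cells <- tibble::tibble(road = rc$Roads, row = rc$row, col = rc$col)

  we <- read_csv_plain(file.path(path, "weather_events.csv"))
  evs <- tolower(names(we)[-1])
  weather_events <- tibble::tibble(
    event = evs,
    duration = as.numeric(unlist(we[grepl("^Duration", we$Event), -1])),
    factor = as.numeric(unlist(we[grepl("^Penalty", we$Event), -1])))

  met <- read_csv_plain(file.path(path, "meteorology.csv"))
  wd <- tidyr::pivot_longer(met, dplyr::all_of(MONTHS3), names_to = "month",
                            values_to = "days")
  weather_days <- tibble::tibble(event = tolower(wd[[1]]),
                                 month = match(wd$month, MONTHS3),
                                 days = as.numeric(wd$days))

  fe <- read_csv_plain(file.path(path, "festivities.csv"))
  fe <- fe[toupper(fe$Type) != "TOTAL", ]
  fd <- tidyr::pivot_longer(fe, dplyr::all_of(MONTHS3), names_to = "month",
                            values_to = "days")
  type_map <- c("local events" = "local_events", "roads closed" = "roads_closed")
  festivity_days <- tibble::tibble(type = unname(type_map[tolower(fd$Type)]),
                                   month = match(fd$month, MONTHS3),
                                   days = as.numeric(fd$days))

  st <- cfg$service_times
  service_times <- list(prep = unlist(st$prep), on_scene = unlist(st$on_scene),
                        at_hospital = unlist(st$at_hospital))

  ems_scenario(
    name = cfg$name, grid = grid,
    towns = tibble::tibble(town = towns$Towns, row = towns$row, col = towns$col,
                           population = as.numeric(towns$Pop),
                           settlement = as.logical(towns$settlement)),
    accident_rates = rates, road_cells = road_cells,
    weather_events = weather_events, weather_days = weather_days,
    hotel_stays = hotel, festivity_days = festivity_days,
    service_times = service_times,
    horizon_days = cfg$horizon_days, replications = cfg$replications,
    ambulances = cfg$ambulances, thresholds = unlist(cfg$thresholds),
    stress_multiplier = cfg$stress_multiplier, seed = cfg$seed,
    year = cfg$year, congestion_extra_min = cfg$congestion_extra_min,
    weekend_uplift = cfg$weekend_uplift,
    congestion_factor = cfg$congestion_factor,
    festivity_factor = cfg$festivity_factor,
    required_units = cfg$required_units,
    dispatch_from_hospital = cfg$dispatch_from_hospital,
    storm_as = cfg$storm_as, cell_size = cfg$cell_size)
}

#' Export indicator results as CSV
#'
#' Writes `phi.csv` (coverage per replication plus the cross-replication
#' mean), `town_pi.csv` and `occupation.csv` into a directory. Values are
#' written losslessly: [read_indicators()] reproduces them bit-exactly.
#'
#' @param x An `ems_sim` or `ems_replicates` object.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
export_indicators <- function(x, path) {
  if (!inherits(x, c("ems_sim", "ems_replicates")))
    ems_abort("results must be a finalized ems_sim or ems_replicates object",
              "ems_validation_error")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "ems_sim")) {
    phi <- tibble::tibble(rep = "1", k = x$phi$k, phi = x$phi$phi)
    phi <- rbind(phi, tibble::tibble(rep = "mean", k = x$phi$k, phi = x$phi$phi))
    town <- x$town_pi
    occ <- x$occupation
  } else {
    per <- dplyr::bind_rows(lapply(seq_along(x$runs), function(r)
      tibble::tibble(rep = as.character(r), k = x$runs[[r]]$phi$k,
                     phi = x$runs[[r]]$phi$phi)))
    phi <- rbind(per, tibble::tibble(rep = "mean", k = x$phi_mean$k,
                                     phi = x$phi_mean$phi))
    town <- x$town_pi_mean
    occ <- x$occupation_mean
  }
  write_csv_exact(phi, file.path(path, "phi.csv"))
  write_csv_exact(town, file.path(path, "town_pi.csv"))
  write_csv_exact(occ, file.path(path, "occupation.csv"))
  invisible(path)
}

#' Re-load exported indicators
#'
#' @param path Directory written by [export_indicators()].
#' @return List of tibbles `phi`, `town_pi`, `occupation`.
#' @export
read_indicators <- function(path) {
  list(phi = read_csv_plain(file.path(path, "phi.csv")),
       town_pi = read_csv_plain(file.path(path, "town_pi.csv")),
       occupation = read_csv_plain(file.path(path, "occupation.csv")))
}

#' Export isochrone bands as GeoJSON
#'
#' Partitions the grid into isochrone bands `[0, k1]`, `(k1, k2]`, ...,
#' plus a beyond-the-largest-threshold band that also holds unreachable
#' cells, and writes one MultiPolygon feature per band (one square ring per
#' cell, in abstract grid coordinates scaled by `cell_size`; no geographic
#' CRS is claimed). Features carry the band label, upper threshold and a
#' green-to-red colour key.
#'
#' @param field An `ems_field` (e.g. from [shortest_time_field()] or a
#'   simulation's time-averaged rescue field).
#' @param thresholds Ascending band thresholds K in minutes.
#' @param path Optional file to write.
#' @param cell_size Edge length of one cell in output coordinates.
#' @return The GeoJSON structure as a list, invisibly when `path` is given.
#' @export
export_isochrone_bands <- function(field, thresholds, path = NULL,
                                   cell_size = 1) {
  if (length(field$minutes) == 0)
    ems_abort("empty grid", "ems_validation_error")
  K <- as.numeric(thresholds)
  if (length(K) == 0 || any(diff(K) <= 0) || any(K <= 0))
    ems_abort("thresholds must be strictly ascending and > 0",
              "ems_validation_error")
  nK <- length(K)
  labels <- c(sprintf("[0,%g]", K[1]),
              if (nK > 1) sprintf("(%g,%g]", K[-nK], K[-1]),
              sprintf(">%g", K[nK]))
  cols <- grDevices::hcl.colors(nK + 1, "RdYlGn", rev = TRUE)
  m <- field$minutes
  band <- findInterval(m, c(K, Inf), left.open = TRUE) + 1L
  band[!is.finite(m)] <- nK + 1L
  id <- seq_along(m)
  row <- (id - 1L) %/% field$ncol
  col <- (id - 1L) %% field$ncol
  features <- lapply(seq_len(nK + 1L), function(b) {
    cells <- which(band == b)
    rings <- lapply(cells, function(i) {
      x0 <- col[i] * cell_size; y0 <- row[i] * cell_size
      list(list(c(x0, y0), c(x0 + cell_size, y0),
                c(x0 + cell_size, y0 + cell_size), c(x0, y0 + cell_size),
                c(x0, y0)))
    })
    list(type = "Feature",
         properties = list(band = labels[b],
                           k_max = if (b <= nK) K[b] else NA,
                           n_cells = length(cells), color = cols[b]),
         geometry = list(type = "MultiPolygon", coordinates = rings))
  })
  geo <- list(type = "FeatureCollection",
              properties = list(kind = field$kind, cell_size = cell_size),
              features = features)
  if (!is.null(path)) {
    jsonlite::write_json(geo, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(geo))
  }
  geo
}
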