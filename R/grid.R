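#' Build a grid road network
#'
#' The region is modelled as a rectangular lattice of cells. A cell is part of
#' the road network when it carries a finite base traversal time in minutes;
#' the EMS hub, hospitals and towns sit on road cells. Ambulances move between
#' 4-neighbouring road cells; crossing from one cell to the next costs the
#' mean of the two cells' traversal times (half a cell is traversed on each
#' side of the boundary), so travel times are symmetric and the time to the
#' i-th cell of a uniform 1-minute road is exactly i minutes.
#'
#' @param cells A data frame with one row per non-empty cell and columns
#'   `row`, `col` (0-based grid coordinates), `minutes` (base traversal time,
#'   > 0), and optionally logical `hub`, `hospital` and a character `town`
#'   (town name, `NA` where none).
#' @param nrow,ncol Grid dimensions; default to the smallest grid containing
#'   all cells.
#' @return An object of class `ems_grid`.
#' @examples
#' g <- ems_grid(data.frame(row = 0, col = 0:9, minutes = 1,
#'                          hub = c(TRUE, rep(FALSE, 9)),
#'                          hospital = c(TRUE, rep(FALSE, 9))))
#' shortest_time_field(g, c(0, 0))
#' @export
ems_grid <- function(cells, nrow = NULL, ncol = NULL) {
  cells <- tibble::as_tibble(cells)
  if (!all(c("row", "col", "minutes") %in% names(cells)))
    ems_abort("grid cells need columns row, col, minutes", "ems_validation_error")
  if (!"hub" %in% names(cells)) cells$hub <- FALSE
  if (!"hospital" %in% names(cells)) cells$hospital <- FALSE
  if (!"town" %in% names(cells)) cells$town <- NA_character_
  cells$hub <- as.logical(cells$hub)
  cells$hospital <- as.logical(cells$hospital)
  nrow <- nrow %||% (max(cells$row) + 1L)
  ncol <- ncol %||% (max(cells$col) + 1L)
  if (any(cells$row < 0 | cells$row >= nrow | cells$col < 0 | cells$col >= ncol))
    ems_abort("grid cells outside stated dimensions", "ems_validation_error")
  if (any(duplicated(cells[c("row", "col")])))
    ems_abort("duplicated grid cells", "ems_validation_error")
  if (any(!is.finite(cells$minutes) | cells$minutes <= 0))
    ems_abort("cell traversal minutes must be finite and > 0", "ems_validation_error")
  if (sum(cells$hub) != 1L)
    ems_abort("grid must contain exactly one hub cell", "ems_validation_error")
  if (sum(cells$hospital) < 1L)
    ems_abort("grid must contain at least one hospital cell", "ems_validation_error")

  n <- as.integer(nrow) * as.integer(ncol)
  id <- cell_index(cells$row, cells$col, ncol)
  minutes <- rep(Inf, n)
  minutes[id] <- cells$minutes
  road <- is.finite(minutes)

  # adjacency over road cells, neighbours in lexicographic (row, col) order
  adj <- vector("list", n)
  rows <- (seq_len(n) - 1L) %/% ncol
  cols <- (seq_len(n) - 1L) %% ncol
  for (u in which(road)) {
    r <- rows[u]; cc <- cols[u]
    nb <- integer(0)
    if (r > 0L && road[u - ncol]) nb <- c(nb, u - ncol)
    if (cc > 0L && road[u - 1L]) nb <- c(nb, u - 1L)
    if (cc < ncol - 1L && road[u + 1L]) nb <- c(nb, u + 1L)
    if (r < nrow - 1L && road[u + ncol]) nb <- c(nb, u + ncol)
    adj[[u]] <- nb
  }

  g <- structure(list(
    nrow = as.integer(nrow), ncol = as.integer(ncol), n_cells = n,
    cells = cells[order(id), ], minutes = minutes, road = road, adj = adj,
    hub = id[cells$hub], hospitals = sort(id[cells$hospital]),
    towns = stats::setNames(id[!is.na(cells$town)],
                            cells$town[!is.na(cells$town)])
  ), class = "ems_grid")

  # one connected road component containing hub, hospitals and towns
  comp <- reachable_cells(g, g$hub)
  if (!all(which(road) %in% comp))
    ems_abort("road cells do not form one connected component with the hub",
              "ems_validation_error")
  g
}

cell_index <- function(row, col, ncol) as.integer(row) * as.integer(ncol) + as.integer(col) + 1L

#' @export
print.ems_grid <- function(x, ...) {
  cat(sprintf("<ems_grid> %d x %d cells, %d road cells, %d hospital(s), %d town cells\n",
              x$nrow, x$ncol, sum(x$road), length(x$hospitals), length(x$towns)))
  invisible(x)
}

# id -> (row, col)
cell_rc <- function(grid, id) {
  cbind(row = (id - 1L) %/% grid$ncol, col = (id - 1L) %% grid$ncol)
}

rc_to_id <- function(grid, cell) {
  if (length(cell) != 2) ems_abort("cell must be c(row, col)", "ems_validation_error")
  if (cell[1] < 0 || cell[1] >= grid$nrow || cell[2] < 0 || cell[2] >= grid$ncol)
    ems_abort("cell outside the grid", "ems_validation_error")
  cell_index(cell[1], cell[2], grid$ncol)
}

# breadth-first reachability over road cells
reachable_cells <- function(grid, source) {
  seen <- logical(grid$n_cells)
  seen[source] <- TRUE
  frontier <- source
  while (length(frontier)) {
    nxt <- unique(unlist(grid$adj[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

# cell + its 8 surrounding cells, restricted to road cells (congestion extent)
neighbourhood9 <- function(grid, id) {
  rc <- cell_rc(grid, id)
  r <- rc[1] + c(-1, -1, -1, 0, 0, 0, 1, 1, 1)
  cc <- rc[2] + c(-1, 0, 1, -1, 0, 1, -1, 0, 1)
  keep <- r >= 0 & r < grid$nrow & cc >= 0 & cc < grid$ncol
  ids <- cell_index(r[keep], cc[keep], grid$ncol)
  ids[grid$road[ids]]
}

#' Construct a travel-time penalty overlay
#'
#' Overlays multiply base traversal times while active. Weather overlays
#' (`rain`, `snow`, `fog`, `ice`) carry the penalty factor of the event type
#' and usually cover the whole network; simultaneous weather events combine by
#' taking the maximum factor, not the product. `congestion` (around an
#' accident) and `festivity` (road-closure days) each double times on top of
#' the weather factor.
#'
#' @param cause One of `"rain"`, `"snow"`, `"fog"`, `"ice"`, `"congestion"`,
#'   `"festivity"`.
#' @param factor Multiplicative penalty, >= 1.
#' @param start,end Active window in simulated minutes, `end > start`.
#' @param cells Integer cell ids affected, or `NULL` for the whole network.
#' @return A one-row tibble; rows from several calls can be `rbind`-ed into an
#'   overlay table.
#' @export
penalty_overlay <- function(cause, factor, start, end, cells = NULL) {
  causes <- c("rain", "snow", "fog", "ice", "congestion", "festivity")
  if (!cause %in% causes)
    ems_abort(paste("unknown overlay cause:", cause), "ems_validation_error")
  if (factor < 1) ems_abort("overlay factor must be >= 1", "ems_validation_error")
  if (!(end > start)) ems_abort("overlay end must exceed start", "ems_validation_error")
  tibble::tibble(cause = cause, factor = as.numeric(factor),
                 start = as.numeric(start), end = as.numeric(end),
                 cells = list(cells))
}

WEATHER_CAUSES <- c("rain", "snow", "fog", "ice")

#' Effective traversal time of cells under active penalties
#'
#' The effective time of a road cell at instant `t` is its base time times the
#' maximum active weather factor (1 when no weather event is active), times the
#' congestion factor when a congestion overlay covers the cell, times the
#' festivity factor when a road-closure overlay is active, times the stress
#' multiplier. Non-road cells have effective time `Inf`.
#'
#' @param grid An [ems_grid()].
#' @param cell `c(row, col)` of a single cell, or `NULL` for the whole grid.
#' @param t Instant in simulated minutes at which overlays are evaluated.
#' @param overlays Overlay table from [penalty_overlay()] rows, or `NULL`.
#' @param stress Global stress multiplier (> 0), default 1.
#' @return Minutes for the requested cell, or the full per-cell vector when
#'   `cell` is `NULL`.
#' @export
effective_traversal_time <- function(grid, cell = NULL, t = 0, overlays = NULL,
                                     stress = 1) {
  w <- effective_minutes(grid, t, overlays, stress)
  if (is.null(cell)) w else w[rc_to_id(grid, cell)]
}

effective_minutes <- function(grid, t, overlays, stress) {
  w <- grid$minutes * stress
  if (is.null(overlays) || nrow(overlays) == 0) return(w)
  act <- overlays[overlays$start <= t & t < overlays$end, ]
  if (nrow(act) == 0) return(w)
  wfac <- rep(1, grid$n_cells)
  cfac <- rep(1, grid$n_cells)
  ffac <- 1
  for (i in seq_len(nrow(act))) {
    ids <- act$cells[[i]] %||% which(grid$road)
    if (act$cause[i] %in% WEATHER_CAUSES) {
      wfac[ids] <- pmax(wfac[ids], act$factor[i])
    } else if (act$cause[i] == "congestion") {
      cfac[ids] <- pmax(cfac[ids], act$factor[i])
    } else { # festivity: whole-network doubling
      ffac <- max(ffac, act$factor[i])
    }
  }
  w * wfac * cfac * ffac
}

# Dijkstra over road cells; edge cost (w[u] + w[v]) / 2. O(n^2), n = road cells.
dijkstra_field <- function(grid, source, w) {
  dist <- rep(Inf, grid$n_cells)
  if (!grid$road[source]) return(dist)
  dist[source] <- 0
  done <- logical(grid$n_cells)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    nb <- grid$adj[[u]]
    if (length(nb)) {
      nd <- dist[u] + (w[u] + w[nb]) / 2
      upd <- nd < dist[nb]
      dist[nb[upd]] <- nd[upd]
    }
  }
  dist
}

dijkstra_route <- function(grid, source, target, w) {
  dist <- rep(Inf, grid$n_cells)
  prev <- integer(grid$n_cells)
  dist[source] <- 0
  done <- logical(grid$n_cells)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])] # ties: lowest cell id, i.e. lexicographic
    if (u == target) break
    done[u] <- TRUE
    for (v in grid$adj[[u]]) { # neighbours visited in lexicographic order
      nd <- dist[u] + (w[u] + w[v]) / 2
      if (nd < dist[v]) { # strict: first (lexicographic) shortest path kept
        dist[v] <- nd
        prev[v] <- u
      }
    }
  }
  if (!is.finite(dist[target])) return(NULL)
  path <- target
  while (path[1] != source) path <- c(prev[path[1]], path)
  list(path = path, duration = dist[target])
}

#' Single-source shortest-time field
#'
#' Exact minimal travel times (minutes) from a source cell to every cell of
#' the road network, with per-cell effective traversal times frozen at the
#' evaluation instant `t`. This is the "time distance" companion of the road
#' grid; unreachable and non-road cells get `Inf`.
#'
#' @inheritParams effective_traversal_time
#' @param source `c(row, col)` of the source cell (must be a road cell).
#' @return An `ems_field` object; `as_tibble()` turns it into
#'   `(row, col, minutes)` rows.
#' @export
shortest_time_field <- function(grid, source, t = 0, overlays = NULL, stress = 1) {
  src <- rc_to_id(grid, source)
  if (!grid$road[src])
    ems_abort("source is not a road cell", "ems_validation_error")
  w <- effective_minutes(grid, t, overlays, stress)
  new_field(dijkstra_field(grid, src, w), grid, kind = "travel",
            source = src, at = t)
}

new_field <- function(minutes, grid, kind, source = NA_integer_, at = NA_real_) {
  structure(list(minutes = minutes, nrow = grid$nrow, ncol = grid$ncol,
                 road = grid$road, kind = kind, source = source, at = at),
            class = "ems_field")
}

#' @export
print.ems_field <- function(x, ...) {
  fin <- x$minutes[is.finite(x$minutes)]
  cat(sprintf("<ems_field: %s> %d x %d grid, %d finite cells, range %.1f-%.1f min\n",
              x$kind, x$nrow, x$ncol, length(fin),
              if (length(fin)) min(fin) else NA, if (length(fin)) max(fin) else NA))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble ems_field
#' @export
as_tibble.ems_field <- function(x, ...) {
  id <- seq_along(x$minutes)
  tibble::tibble(row = (id - 1L) %/% x$ncol, col = (id - 1L) %% x$ncol,
                 minutes = x$minutes)[x$road | is.finite(x$minutes), ]
}

#' Shortest route between two cells
#'
#' Returns the path (as `(row, col)` rows) and duration of a shortest route
#' under the effective traversal times frozen at `t`. Ties between equal-time
#' routes are broken deterministically by exploring neighbours in
#' lexicographic `(row, col)` order.
#'
#' @inheritParams shortest_time_field
#' @param from,to `c(row, col)` endpoints; both must be road cells.
#' @return A list with `path` (tibble of `row`, `col`; empty when
#'   `from == to`... the path includes both endpoints otherwise) and
#'   `duration` in minutes.
#' @export
route <- function(grid, from, to, t = 0, overlays = NULL, stress = 1) {
  src <- rc_to_id(grid, from); dst <- rc_to_id(grid, to)
  if (!grid$road[src] || !grid$road[dst])
    ems_abort("route endpoints must be road cells", "ems_validation_error")
  if (src == dst)
    return(list(path = tibble::tibble(row = integer(), col = integer()),
                duration = 0))
  w <- effective_minutes(grid, t, overlays, stress)
  r <- dijkstra_route(grid, src, dst, w)
  if (is.null(r))
    ems_abort("destination unreachable from source", "ems_unreachable_error")
  rc <- cell_rc(grid, r$path)
  list(path = tibble::tibble(row = rc[, "row"], col = rc[, "col"]),
       duration = r$duration)
}
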