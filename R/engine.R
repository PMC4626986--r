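# Event-driven simulation core.
#
# Future events are: environment changes (day rollovers, weather event
# starts/ends, road-closure day boundaries), congestion expirations,
# ambulance stage completions and accident occurrences; simultaneous events
# are executed in that fixed priority order (then by id). Between consecutive
# events every state input of the indicators is frozen except the remaining
# unavailability of busy units, which decreases linearly, so the
# time-weighted indicator integrals (phi_k, pi_k, averaged rescue field) have
# closed forms per interval and are accumulated exactly rather than sampled
# on a tick.

#' Run one replication of the EMS simulation
#'
#' Simulates one horizon of accident generation, weather, population dynamics
#' and the six-task ambulance lifecycle (preparation, travel to scene,
#' on-scene assistance, travel to hospital, hospital drop-off, return to
#' base), with FIFO dispatch of the closest free ambulance, and accumulates
#' the dynamic coverage indicators.
#'
#' @param scenario An [ems_scenario()].
#' @param seed Master seed (defaults to the scenario's seed). Substream seeds
#'   for accidents, weather and service times derive from `(seed, rep)`, so
#'   runs with different ambulance counts but the same `(seed, rep)` share
#'   identical random inputs (common random numbers).
#' @param rep Replication index (used in substream derivation).
#' @param ambulances,stress Optional overrides of the scenario's ambulance
#'   count and stress multiplier.
#' @param collect_field If `TRUE`, also accumulate the time-averaged rescue
#'   field over the whole grid (needed for isochrone band export).
#' @param accidents,weather Optional pre-built accident calendar / weather
#'   overlay table, replacing the seeded generators (used to script exact
#'   event sequences).
#' @return An `ems_sim` object; see [tidy.ems_sim()] and [glance.ems_sim()].
#' @export
simulate_ems <- function(scenario, seed = scenario$seed, rep = 0L,
                         ambulances = scenario$ambulances,
                         stress = scenario$stress_multiplier,
                         collect_field = FALSE,
                         accidents = NULL, weather = NULL) {
  sc <- scenario
  grid <- sc$grid
  horizon <- sc$horizon_days * 1440
  nu <- as.integer(ambulances)
  if (nu < 1) ems_abort("ambulance count must be >= 1", "ems_validation_error")
  K <- sc$thresholds
  nK <- length(K)

  acc <- accidents %||% sample_accident_calendar(sc, seed, rep, stress = stress)
  wx <- weather %||% sample_weather_calendar(sc, seed, rep)
  fest <- festivity_overlays(sc)

  # global scale s(t): max active weather factor x festivity x stress,
  # piecewise constant between environment events
  env_overlays <- dplyr::bind_rows(wx, fest)
  day_bounds <- 1440 * seq_len(ceiling(sc$horizon_days))
  env_times <- sort(unique(c(
    day_bounds,
    pmax(0, pmin(c(env_overlays$start, env_overlays$end), horizon)))))
  env_times <- env_times[env_times > 0 & env_times <= horizon]
  sbreaks <- c(0, env_times)
  svals <- vapply(sbreaks, function(t) {
    s <- stress
    if (nrow(env_overlays)) {
      act <- env_overlays[env_overlays$start <= t & t < env_overlays$end, ]
      wf <- act$factor[act$cause %in% WEATHER_CAUSES]
      ff <- act$factor[act$cause == "festivity"]
      s <- s * (if (length(wf)) max(wf) else 1) * (if (length(ff)) max(ff) else 1)
    }
    s
  }, numeric(1))
  scale_sf <- step_fun(sbreaks, svals)

  popM <- population_matrix(sc)
  pop_cells <- sc$towns$cell
  town_names <- sc$towns$town
  nP <- length(pop_cells)

  hub <- grid$hub
  hospitals <- grid$hospitals

  # shortest-time fields cached per (source, active congestion signature);
  # congestion modifies which route is shortest, global factors do not
  fcache <- new.env(parent = emptyenv())
  cong_cells <- integer(0)
  sig <- ""
  base_w <- grid$minutes
  w_cong <- base_w
  refresh_congestion <- function(active_cells) {
    cong_cells <<- active_cells
    sig <<- paste(active_cells, collapse = ",")
    w <- base_w
    if (length(active_cells))
      w[active_cells] <- w[active_cells] * sc$congestion_factor
    w_cong <<- w
  }
  get_field <- function(src) {
    key <- paste0(src, "|", sig)
    f <- fcache[[key]]
    if (is.null(f)) {
      f <- dijkstra_field(grid, src, w_cong)
      fcache[[key]] <- f
    }
    f
  }

  # ambulance state
  stage <- rep("free", nu)
  stage_start <- rep(0, nu)
  stage_end <- rep(Inf, nu)
  loc <- rep(hub, nu)
  avail_est <- rep(0, nu)
  cur_acc <- rep(NA_integer_, nu)
  cur_hosp <- rep(NA_integer_, nu)

  nA <- nrow(acc)
  queue <- integer(0)
  needed <- rep(sc$required_units, nA)
  # accident log
  a_assign <- a_scene <- a_sdep <- a_clear <- rep(NA_real_, nA)
  a_unit <- rep(NA_integer_, nA)
  a_uncov <- rep(FALSE, nA)
  cong_end <- rep(NA_real_, nA)   # active from acc time; NA = not active
  cong_sets <- vector("list", nA)

  # logs and accumulators
  log_unit <- integer(0); log_stage <- character(0)
  log_s <- numeric(0); log_e <- numeric(0)
  push_log <- function(u, st, s0, e0) {
    log_unit[[length(log_unit) + 1L]] <<- u
    log_stage[[length(log_stage) + 1L]] <<- st
    log_s[[length(log_s) + 1L]] <<- s0
    log_e[[length(log_e) + 1L]] <<- e0
  }
  phi_acc <- numeric(nK)
  pi_acc <- matrix(0, nP, nK, dimnames = list(town_names, NULL))
  field_acc <- if (collect_field) numeric(grid$n_cells) else NULL

  s_cur <- svals[1]

  # remaining-cycle estimate: when the unit will be free at the hub,
  # priced with the current global scale and congestion pattern
  update_avail <- function(i, now) {
    if (stage[i] == "free") { avail_est[i] <<- now; return(invisible()) }
    aid <- cur_acc[i]
    rem <- stage_end[i] - now
    st <- stage[i]
    if (st %in% c("prep", "to_scene", "on_scene")) {
      scell <- acc$cell[aid]
      if (st == "prep") rem <- rem + s_cur * get_field(loc[i])[scell]
      if (st %in% c("prep", "to_scene")) rem <- rem + acc$on_scene[aid]
      dh <- vapply(hospitals, function(h) get_field(h)[scell], numeric(1))
      hbi <- order(dh, hospitals)[1]
      rem <- rem + s_cur * dh[hbi] + acc$at_hospital[aid] +
        s_cur * get_field(hospitals[hbi])[hub]
    } else if (st == "to_hospital") {
      rem <- rem + acc$at_hospital[aid] + s_cur * get_field(cur_hosp[i])[hub]
    } else if (st == "at_hospital") {
      rem <- rem + s_cur * get_field(cur_hosp[i])[hub]
    } # returning: rem is just the leg remainder
    avail_est[i] <<- now + rem
  }

  # exact indicator integration over [t1, t2)
  accumulate <- function(t1, t2) {
    t2 <- min(t2, horizon)
    if (t2 <= t1) return(invisible())
    day <- min(floor(t1 / 1440) + 1L, nrow(popM))
    pops <- popM[day, ]
    total <- sum(pops)
    dt <- t2 - t1
    # per-unit wait anchor a_i and travel vector b_i to population cells
    a <- ifelse(stage == "free", t1, pmax(avail_est, t1))
    srcs <- ifelse(stage == "free", loc,
                   ifelse(rep(sc$dispatch_from_hospital, nu) &
                            stage %in% c("to_hospital", "at_hospital"),
                          cur_hosp, hub))
    common <- all(srcs == srcs[1])
    bmat <- if (common) {
      matrix(rep(s_cur * get_field(srcs[1])[pop_cells], nu), nP, nu)
    } else {
      vapply(srcs, function(s0) s_cur * get_field(s0)[pop_cells],
             numeric(nP))
    }
    for (j in seq_len(nK)) {
      k <- K[j]
      covstart <- rep(Inf, nP)
      for (i in seq_len(nu)) {
        b <- bmat[, i]
        cs <- ifelse(k >= b, a[i] - (k - b), Inf)
        covstart <- pmin(covstart, cs)
      }
      dur <- pmax(0, t2 - pmax(t1, covstart))
      if (total > 0) phi_acc[j] <<- phi_acc[j] + sum(pops * dur) / total
      pi_acc[, j] <<- pi_acc[, j] + dur
    }
    if (collect_field) {
      # mean over the interval of the common wait max(0, amin - t)
      amin <- min(a)
      mw <- if (amin <= t1) 0
      else if (amin >= t2) amin - (t1 + t2) / 2
      else (amin - t1)^2 / 2 / dt
      fvec <- if (common) get_field(srcs[1])
      else {
        # cellwise min of per-unit rescue times at the interval midpoint
        best <- rep(Inf, grid$n_cells)
        mid <- (t1 + t2) / 2
        for (i in seq_len(nu))
          best <- pmin(best, max(0, a[i] - mid) / s_cur + get_field(srcs[i]))
        mw <- 0
        best
      }
      field_acc <<- field_acc + (mw + s_cur * fvec) * dt
    }
    invisible()
  }

  try_dispatch <- function(now) {
    repeat {
      if (!length(queue)) break
      free <- which(stage == "free")
      if (!length(free)) break
      aid <- queue[1]
      d <- vapply(free, function(i) get_field(loc[i])[acc$cell[aid]], numeric(1))
      if (all(is.infinite(d))) {
        a_uncov[aid] <<- TRUE
        cong_end[aid] <<- now   # never served: release congestion now
        queue <<- queue[-1]
        warning(sprintf("accident %d at cell %d unreachable from any unit: flagged uncoverable",
                        aid, acc$cell[aid]), call. = FALSE)
        next
      }
      u <- free[order(d, free)][1]
      if (is.na(a_assign[aid])) { a_assign[aid] <<- now; a_unit[aid] <<- u }
      needed[aid] <<- needed[aid] - 1L
      if (needed[aid] <= 0L) queue <<- queue[-1]
      stage[u] <<- "prep"; stage_start[u] <<- now
      stage_end[u] <<- now + acc$prep[aid]
      cur_acc[u] <<- aid
      update_avail(u, now)
    }
    invisible()
  }

  advance_unit <- function(i, now) {
    aid <- cur_acc[i]
    push_log(i, stage[i], stage_start[i], now)
    st <- stage[i]
    if (st == "prep") {
      dur <- s_cur * get_field(loc[i])[acc$cell[aid]]
      stage[i] <<- "to_scene"
    } else if (st == "to_scene") {
      loc[i] <<- acc$cell[aid]
      if (i == a_unit[aid] || is.na(a_scene[aid])) a_scene[aid] <<- now
      dur <- acc$on_scene[aid]
      stage[i] <<- "on_scene"
    } else if (st == "on_scene") {
      if (is.na(a_sdep[aid])) {
        a_sdep[aid] <<- now
        cong_end[aid] <<- now + sc$congestion_extra_min
      }
      dh <- vapply(hospitals, function(h) get_field(h)[loc[i]], numeric(1))
      h <- hospitals[order(dh, hospitals)][1]
      cur_hosp[i] <<- h
      dur <- s_cur * dh[match(h, hospitals)]
      stage[i] <<- "to_hospital"
    } else if (st == "to_hospital") {
      loc[i] <<- cur_hosp[i]
      dur <- acc$at_hospital[aid]
      stage[i] <<- "at_hospital"
    } else if (st == "at_hospital") {
      if (sc$dispatch_from_hospital && length(queue)) {
        # unit is dispatchable at the hospital: free it there and let the
        # dispatcher take it; otherwise it commits to the return leg
        stage[i] <<- "free"
        stage_end[i] <<- Inf
        avail_est[i] <<- now
        if (is.na(a_clear[aid]) && i == a_unit[aid]) a_clear[aid] <<- now
        cur_acc[i] <<- NA_integer_
        try_dispatch(now)
        if (stage[i] == "free") { # nothing took it: return home
          stage[i] <<- "returning"
          stage_start[i] <<- now
          stage_end[i] <<- now + s_cur * get_field(hub)[loc[i]]
          cur_acc[i] <<- aid
          update_avail(i, now)
        }
        return(invisible())
      }
      dur <- s_cur * get_field(hub)[loc[i]]
      stage[i] <<- "returning"
    } else { # returning ends: free at the hub
      loc[i] <<- hub
      stage[i] <<- "free"
      stage_end[i] <<- Inf
      avail_est[i] <<- now
      if (!is.na(aid) && i == a_unit[aid] && is.na(a_clear[aid]))
        a_clear[aid] <<- now
      cur_acc[i] <<- NA_integer_
      try_dispatch(now)
      return(invisible())
    }
    stage_start[i] <<- now
    stage_end[i] <<- now + dur
    update_avail(i, now)
    invisible()
  }

  refresh_congestion(integer(0))
  now <- 0; last <- 0
  ia <- 1L; ie <- 1L
  nE <- length(env_times)
  repeat {
    tA <- if (ia <= nA) acc$time[ia] else Inf
    tE <- if (ie <= nE) env_times[ie] else Inf
    busyu <- which(stage != "free")
    tS <- if (length(busyu)) min(stage_end[busyu]) else Inf
    act_cong <- which(!is.na(cong_end))
    tC <- if (length(act_cong)) min(cong_end[act_cong]) else Inf
    tnext <- min(tE, tC, tS, tA)
    if (!is.finite(tnext)) break
    if (tnext >= horizon && ia > nA && !length(queue) &&
        all(stage == "free") && tE == Inf) break
    accumulate(last, tnext)
    last <- tnext
    now <- tnext
    if (tE <= tnext) {
      s_cur <- step_at(scale_sf, now)
      ie <- ie + 1L
    } else if (tC <= tnext) {
      done <- which(!is.na(cong_end) & cong_end <= now)
      for (d0 in done) { cong_end[d0] <- NA; cong_sets[d0] <- list(NULL) }
      refresh_congestion(unique(unlist(cong_sets[which(!is.na(cong_end))])) %||% integer(0))
    } else if (tS <= tnext) {
      i <- busyu[stage_end[busyu] <= now][1]
      advance_unit(i, now)
    } else {
      cong_sets[[ia]] <- neighbourhood9(grid, acc$cell[ia])
      cong_end[ia] <- Inf   # active until the serving unit departs + extra
      refresh_congestion(unique(unlist(cong_sets[which(!is.na(cong_end))])))
      queue <- c(queue, ia)
      ia <- ia + 1L
      try_dispatch(now)
    }
  }
  accumulate(last, horizon)

  # occupation intervals: clip busy intervals to the horizon, fill gaps with
  # free time
  iv <- tibble::tibble(unit = log_unit, stage = log_stage,
                       start = log_s, end = log_e)
  # units still busy at the horizon contribute their open stage
  for (i in which(stage != "free"))
    iv <- dplyr::add_row(iv, unit = i, stage = stage[i],
                         start = stage_start[i], end = stage_end[i])
  iv$start <- pmin(iv$start, horizon); iv$end <- pmin(iv$end, horizon)
  iv <- iv[iv$end > iv$start, ]
  full <- list()
  for (u in seq_len(nu)) {
    ui <- iv[iv$unit == u, ]
    ui <- ui[order(ui$start), ]
    gap_from <- c(0, ui$end)
    gap_to <- c(ui$start, horizon)
    keep <- gap_to - gap_from > 1e-9
    if (any(keep))
      ui <- dplyr::bind_rows(ui, tibble::tibble(
        unit = u, stage = "free", start = gap_from[keep], end = gap_to[keep]))
    full[[u]] <- ui[order(ui$start), ]
  }
  intervals <- dplyr::bind_rows(full)
  occ <- occupation(intervals, horizon)
  avail_by_unit <- occ$fraction[occ$stage == "free"]

  accidents_log <- tibble::tibble(
    id = acc$id, time = acc$time, road = acc$road, cell = acc$cell,
    unit = a_unit, assigned = a_assign, scene_arrival = a_scene,
    scene_departure = a_sdep, cleared = a_clear,
    response = a_scene - acc$time, uncoverable = a_uncov)

  structure(list(
    scenario_name = sc$name, seed = seed, rep = rep, ambulances = nu,
    stress = stress, horizon = horizon, thresholds = K,
    phi = {
      out <- tibble::tibble(k = K, phi = phi_acc / horizon)
      class(out) <- c("ems_coverage", class(out)); out
    },
    town_pi = tibble::tibble(town = rep(town_names, times = nK),
                             k = rep(K, each = nP),
                             pi = as.vector(pi_acc) / horizon),
    occupation = occ,
    availability = mean(avail_by_unit),
    availability_by_unit = avail_by_unit,
    accidents = accidents_log,
    intervals = intervals,
    field = if (collect_field)
      new_field(field_acc / horizon, grid, kind = "rescue_time_avg")
    else NULL
  ), class = "ems_sim")
}

#' @export
print.ems_sim <- function(x, ...) {
  cat(sprintf(paste0("<ems_sim> %s: c = %d, %d accidents, availability %.1f%%, ",
                     "mean response %.1f min\n"),
              x$scenario_name, x$ambulances, nrow(x$accidents),
              100 * x$availability,
              mean(x$accidents$response, na.rm = TRUE)))
  ph <- x$phi
  cat("  phi_k:", paste(sprintf("%g:%.3f", ph$k, ph$phi), collapse = "  "), "\n")
  invisible(x)
}
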