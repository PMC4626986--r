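#' Replicate a simulation and average across replications
#'
#' Runs `replications` independent one-horizon simulations. Replication `r`
#' draws from substreams derived from `(seed, r)`, so replicate sets run with
#' different ambulance counts or stress multipliers share their random inputs
#' pairwise (common random numbers).
#'
#' @inheritParams simulate_ems
#' @param replications Number of replications (defaults to the scenario's).
#' @return An `ems_replicates` object: per-replication results in `$runs`,
#'   cross-replication mean and sd curves in `$phi_mean`, `$phi_sd`,
#'   `$town_pi_mean`, `$occupation_mean`, and scalar summaries.
#' @export
replicate_ems <- function(scenario, replications = scenario$replications,
                          seed = scenario$seed,
                          ambulances = scenario$ambulances,
                          stress = scenario$stress_multiplier,
                          collect_field = FALSE) {
  if (replications < 1) ems_abort("replications must be >= 1", "ems_validation_error")
  runs <- lapply(seq_len(replications), function(r)
    simulate_ems(scenario, seed = seed, rep = r, ambulances = ambulances,
                 stress = stress, collect_field = collect_field))
  phis <- vapply(runs, function(x) x$phi$phi, numeric(length(scenario$thresholds)))
  phis <- matrix(phis, nrow = length(scenario$thresholds))
  pim <- Reduce(`+`, lapply(runs, function(x) x$town_pi$pi)) / replications
  occm <- Reduce(`+`, lapply(runs, function(x) x$occupation$fraction)) / replications
  phi_mean <- tibble::tibble(k = scenario$thresholds, phi = rowMeans(phis))
  class(phi_mean) <- c("ems_coverage", class(phi_mean))
  structure(list(
    scenario_name = scenario$name, seed = seed, replications = replications,
    ambulances = as.integer(ambulances), stress = stress,
    thresholds = scenario$thresholds,
    runs = runs,
    phi_mean = phi_mean,
    phi_sd = tibble::tibble(k = scenario$thresholds,
                            sd = apply(phis, 1, stats::sd)),
    town_pi_mean = tibble::tibble(town = runs[[1]]$town_pi$town,
                                  k = runs[[1]]$town_pi$k, pi = pim),
    occupation_mean = tibble::tibble(unit = runs[[1]]$occupation$unit,
                                     stage = runs[[1]]$occupation$stage,
                                     fraction = occm),
    availability = mean(vapply(runs, `[[`, numeric(1), "availability")),
    mean_response = mean(unlist(lapply(runs, function(x)
      x$accidents$response[!x$accidents$uncoverable])), na.rm = TRUE),
    n_accidents = mean(vapply(runs, function(x) nrow(x$accidents), numeric(1)))
  ), class = "ems_replicates")
}

#' @export
print.ems_replicates <- function(x, ...) {
  cat(sprintf("<ems_replicates> %s: c = %d, %d reps, availability %.1f%%, mean response %.1f min\n",
              x$scenario_name, x$ambulances, x$replications,
              100 * x$availability, x$mean_response))
  cat("  mean phi_k:", paste(sprintf("%g:%.3f", x$phi_mean$k, x$phi_mean$phi),
                             collapse = "  "), "\n")
  invisible(x)
}

#' Deployment sweep over ambulance counts
#'
#' Replicates the scenario for each staffing level with common random
#' numbers, so differences between levels reflect staffing, not sampling.
#'
#' @inheritParams replicate_ems
#' @param ambulances Integer vector of staffing levels, e.g. `1:3`.
#' @return An `ems_sweep`: named list of `ems_replicates` (`$results`) plus
#'   the [availability_vs_coverage()] `$summary` table.
#' @export
deploy_sweep <- function(scenario, ambulances = 1:3,
                         replications = scenario$replications,
                         seed = scenario$seed,
                         stress = scenario$stress_multiplier) {
  res <- lapply(ambulances, function(c0)
    replicate_ems(scenario, replications = replications, seed = seed,
                  ambulances = c0, stress = stress))
  names(res) <- paste0("c", ambulances)
  structure(list(results = res, summary = availability_vs_coverage(res),
                 ambulances = ambulances, seed = seed),
            class = "ems_sweep")
}

#' @export
print.ems_sweep <- function(x, ...) {
  cat("<ems_sweep> staffing levels:", paste(x$ambulances, collapse = ", "), "\n")
  av <- unique(x$summary[c("c", "availability")])
  for (i in seq_len(nrow(av)))
    cat(sprintf("  c = %d: availability %.1f%%\n", av$c[i], 100 * av$availability[i]))
  invisible(x)
}

#' Static indicators under perfect conditions
#'
#' Coverage with an ambulance always available at the hub, no penalties and
#' static populations: the hub's shortest-time field, the static coverage
#' curve phi_k and the 0/1 per-town coverage pi_k.
#'
#' @param scenario An [ems_scenario()].
#' @return An `ems_static` list: `field` (hub travel-time field), `phi`
#'   (`ems_coverage` tibble) and `town_pi` (tibble `town`, `k`, `pi`).
#' @export
static_indicators <- function(scenario) {
  grid <- scenario$grid
  rc <- cell_rc(grid, grid$hub)
  field <- shortest_time_field(grid, c(rc[1], rc[2]))
  pop <- tibble::tibble(cell = scenario$towns$cell,
                        population = scenario$towns$population)
  K <- scenario$thresholds
  tt <- field$minutes[scenario$towns$cell]
  structure(list(
    field = field,
    phi = coverage_curve(field, pop, K),
    town_pi = tibble::tibble(
      town = rep(scenario$towns$town, times = length(K)),
      k = rep(K, each = nrow(scenario$towns)),
      pi = as.numeric(rep(tt, times = length(K)) <= rep(K, each = length(tt))))
  ), class = "ems_static")
}

#' @export
print.ems_static <- function(x, ...) {
  cat("<ems_static> static coverage:\n")
  cat(" ", paste(sprintf("phi_%g = %.1f%%", x$phi$k, 100 * x$phi$phi),
                 collapse = "  "), "\n")
  invisible(x)
}
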