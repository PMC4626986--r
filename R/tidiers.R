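#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result
#'
#' One row per isochrone threshold with the time-weighted population
#' coverage, plus identifying columns.
#'
#' @param x An `ems_sim` object.
#' @param ... Unused.
#' @return A tibble `ambulances`, `rep`, `k`, `phi`.
#' @method tidy ems_sim
#' @export
tidy.ems_sim <- function(x, ...) {
  tibble::tibble(ambulances = x$ambulances, rep = x$rep,
                 k = x$phi$k, phi = x$phi$phi)
}

#' @rdname tidy.ems_sim
#' @method tidy ems_replicates
#' @export
tidy.ems_replicates <- function(x, ...) {
  dplyr::bind_rows(lapply(x$runs, tidy))
}

#' @rdname tidy.ems_sim
#' @method tidy ems_sweep
#' @export
tidy.ems_sweep <- function(x, ...) {
  dplyr::bind_rows(lapply(x$results, tidy))
}

#' Glance at a simulation result
#'
#' @param x An `ems_sim`, `ems_replicates` or `ems_sweep` object.
#' @param ... Unused.
#' @return A one-row tibble (one row per staffing level for sweeps) with the
#'   ambulance count, accident count, mean response time (minutes), mean
#'   availability and the Golden-Hour (largest-threshold) coverage.
#' @method glance ems_sim
#' @export
glance.ems_sim <- function(x, ...) {
  tibble::tibble(
    ambulances = x$ambulances, replications = 1L,
    n_accidents = nrow(x$accidents),
    mean_response = mean(x$accidents$response[!x$accidents$uncoverable],
                         na.rm = TRUE),
    availability = x$availability,
    phi_max_k = x$phi$phi[which.max(x$phi$k)])
}

#' @rdname glance.ems_sim
#' @method glance ems_replicates
#' @export
glance.ems_replicates <- function(x, ...) {
  tibble::tibble(
    ambulances = x$ambulances, replications = x$replications,
    n_accidents = x$n_accidents, mean_response = x$mean_response,
    availability = x$availability,
    phi_max_k = x$phi_mean$phi[which.max(x$phi_mean$k)])
}

#' @rdname glance.ems_sim
#' @method glance ems_sweep
#' @export
glance.ems_sweep <- function(x, ...) {
  dplyr::bind_rows(lapply(x$results, glance))
}
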