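#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a coverage curve
#'
#' Cumulative population coverage against the isochrone threshold.
#'
#' @param object An `ems_coverage` tibble (from [coverage_curve()], a
#'   simulation's `$phi`, or a replicate set's `$phi_mean`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ems_coverage
#' @export
autoplot.ems_coverage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$phi)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "isochrone threshold k (min)",
                  y = expression(phi[k]),
                  title = "Population coverage") +
    ggplot2::theme_minimal()
}

#' Plot a travel-time or rescue-time field
#'
#' Tile map of the per-cell minutes, banded at the given thresholds.
#'
#' @param object An `ems_field`.
#' @param thresholds Band limits in minutes.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ems_field
#' @export
autoplot.ems_field <- function(object, thresholds = c(10, 20, 30, 40, 50, 60),
                               ...) {
  df <- as_tibble(object)
  df <- df[is.finite(df$minutes), ]
  K <- thresholds
  labs <- c(sprintf("[0,%g]", K[1]),
            if (length(K) > 1) sprintf("(%g,%g]", K[-length(K)], K[-1]),
            sprintf(">%g", K[length(K)]))
  df$band <- factor(labs[pmin(findInterval(df$minutes, c(K, Inf),
                                           left.open = TRUE) + 1L,
                              length(labs))], levels = labs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$band)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = stats::setNames(
        grDevices::hcl.colors(length(labs), "RdYlGn", rev = TRUE), labs),
      drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "minutes", x = NULL, y = NULL,
                  title = sprintf("%s time field", object$kind)) +
    ggplot2::theme_minimal()
}

#' Plot an occupation report
#'
#' Stacked shares of each unit's horizon across the four activity stages.
#'
#' @param object An `ems_occupation` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ems_occupation
#' @export
autoplot.ems_occupation <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$unit), y = .data$fraction,
                               fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "ambulance", y = "share of horizon",
                  title = "Ambulance occupation") +
    ggplot2::theme_minimal()
}

#' Plot availability against coverage across staffing levels
#'
#' Coverage curves per ambulance count with the availability level as a
#' dashed reference line, the summary view used for deployment decisions.
#'
#' @param object An `ems_sweep` from [deploy_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ems_sweep
#' @export
autoplot.ems_sweep <- function(object, ...) {
  df <- object$summary
  df$c <- factor(df$c)
  av <- unique(df[c("c", "availability")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$phi,
                                   colour = .data$c)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(data = av,
                        ggplot2::aes(yintercept = .data$availability,
                                     colour = .data$c),
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "isochrone threshold k (min)", y = expression(phi[k]),
                  colour = "ambulances",
                  title = "Coverage and availability by staffing level") +
    ggplot2::theme_minimal()
}
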