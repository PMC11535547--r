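# Broom-style tidiers and ggplot2 methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a steady-state result
#'
#' @param x A `steady_state_result`.
#' @param ... Unused.
#' @return A tibble with `species`, `type` (cell/mediator), `value`, `unit`.
#' @method tidy steady_state_result
#' @export
tidy.steady_state_result <- function(x, ...) {
  tibble::tibble(
    species = c(names(x$state$cell_density), names(x$state$mediator_conc)),
    type = rep(c("cell", "mediator"),
               c(length(x$state$cell_density),
                 length(x$state$mediator_conc))),
    value = c(unname(x$state$cell_density), unname(x$state$mediator_conc)),
    unit = rep(c("cells/mL", "ng/mL"),
               c(length(x$state$cell_density),
                 length(x$state$mediator_conc))))
}

#' @rdname tidy.steady_state_result
#' @method glance steady_state_result
#' @export
glance.steady_state_result <- function(x, ...) {
  tibble::tibble(converged = x$converged, residual_norm = x$residual_norm,
                 das28 = das28(x$state))
}

#' Glance at a selected virtual population
#'
#' @param x A population tibble carrying a `selection` attribute (from
#'   [select_vpop()]).
#' @param ... Unused.
#' @return A one-row tibble: cohort/plausible/selected counts, convergence
#'   flag and the worst normalized residual.
#' @method glance ra_population
#' @export
glance.ra_population <- function(x, ...) {
  sel <- attr(x, "selection")
  tibble::tibble(
    n_cohort = nrow(x),
    n_plausible = sum(x$plausible, na.rm = TRUE),
    n_selected = if (!is.null(sel)) sel$n_selected else NA_integer_,
    selection_converged = if (!is.null(sel)) sel$converged else NA,
    max_abs_scaled_residual = if (!is.null(sel))
      max(abs(sel$residuals$residual / sel$residuals$tol), na.rm = TRUE)
    else NA_real_)
}

#' Tidy the selection residual report
#'
#' @param x A population tibble from [select_vpop()].
#' @param ... Unused.
#' @return The residual tibble: `trial`, `quantity`, `target`, `achieved`,
#'   `residual`, `tol`.
#' @method tidy ra_population
#' @export
tidy.ra_population <- function(x, ...) {
  sel <- attr(x, "selection")
  if (is.null(sel)) stop("population has no selection attached",
                         call. = FALSE)
  sel$residuals
}

#' Plot a simulated time course
#'
#' Faceted log-scale trajectories of all species, or a chosen subset.
#'
#' @param object An `ra_timecourse` tibble.
#' @param species Species to show (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ra_timecourse
#' @export
autoplot.ra_timecourse <- function(object,
                                   species = c(RA_CELLS, RA_MEDIATORS),
                                   ...) {
  long <- tidyr::pivot_longer(object, dplyr::all_of(species),
                              names_to = "species", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "density (cells/mL) or conc (ng/mL)")
}

#' Tornado plot of a local sensitivity analysis
#'
#' @param object A `local_sensitivity` tibble.
#' @param top Number of parameters to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot local_sensitivity
#' @export
autoplot.local_sensitivity <- function(object, top = 20, ...) {
  d <- utils::head(object, top)
  long <- tidyr::pivot_longer(d, c("pct_change_up", "pct_change_down"),
                              names_to = "direction", values_to = "pct")
  long$direction <- ifelse(long$direction == "pct_change_up",
                           "2x increase", "2x decrease")
  long$parameter <- factor(long$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pct, y = .data$parameter,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "identity", alpha = 0.8) +
    ggplot2::scale_fill_manual(values = c("2x increase" = "#2166ac",
                                          "2x decrease" = "#b2182b")) +
    ggplot2::labs(x = "% change in model DAS28-CRP", y = NULL,
                  fill = NULL)
}

#' Plot Sobol indices
#'
#' @param object A `sobol_result` tibble.
#' @param top Number of parameters to show (by total order).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sobol_result
#' @export
autoplot.sobol_result <- function(object, top = 20, ...) {
  d <- object[order(-object$total_order), ]
  d <- utils::head(d, top)
  long <- tidyr::pivot_longer(d, c("first_order", "total_order"),
                              names_to = "order", values_to = "index")
  long$ci <- ifelse(long$order == "first_order", d$first_ci[match(
    long$parameter, d$parameter)], d$total_ci[match(long$parameter,
                                                    d$parameter)])
  long$parameter <- factor(long$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$parameter,
                                     fill = .data$order)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(ggplot2::aes(xmin = .data$index - .data$ci,
                                        xmax = .data$index + .data$ci),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.3) +
    ggplot2::scale_fill_manual(values = c(first_order = "#b2182b",
                                          total_order = "#2166ac")) +
    ggplot2::labs(x = "Sobol index", y = NULL, fill = NULL)
}

#' Calibration plot of a selected virtual population
#'
#' Achieved versus target values for every calibrated quantity, with the
#' tolerance band.
#'
#' @param population A population tibble from [select_vpop()].
#' @return A ggplot object.
#' @export
plot_vpop_calibration <- function(population) {
  res <- tidy.ra_population(population)
  res$label <- paste(res$trial, res$quantity)
  ggplot2::ggplot(res, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_errorbar(ggplot2::aes(xmin = .data$target - .data$tol,
                                        xmax = .data$target + .data$tol),
                           width = 0.3, color = "grey55") +
    ggplot2::geom_point(ggplot2::aes(x = .data$target), shape = 3,
                        size = 3, color = "#b2182b") +
    ggplot2::geom_point(ggplot2::aes(x = .data$achieved), size = 2,
                        color = "#2166ac") +
    ggplot2::labs(x = "fraction / score", y = NULL)
}

#' @importFrom rlang .data
NULL
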