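# Plotting helpers for grid results.

#' Plot a long-format grid results table
#'
#' Draws the computed quantity against the innermost sweep parameter, one
#' colored line per value of the outermost sweep parameter, faceted by
#' quantity when several were requested. This mirrors how the power and
#' effect-size curves are usually displayed.
#'
#' @param object,x A results table from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' res <- run_grid(scenario_grid(scenario(),
#'                               list(r_x = c(1.5, 2), k = seq(0, 2, 0.5))),
#'                 outputs = "power_interaction")
#' autoplot(res)
#' @method autoplot epi_grid_result
#' @export
autoplot.epi_grid_result <- function(object, ...) {
  sweeps <- attr(object, "sweeps")
  if (is.null(sweeps) || length(sweeps) == 0) {
    abort("cannot autoplot a grid without sweeps",
          class = "epipower_error_invalid_parameter")
  }
  xnm <- resolve_sweep_fields(names(sweeps)[[length(sweeps)]])[1]
  p <- ggplot2::ggplot(
    dplyr::filter(object, .data$feasible),
    ggplot2::aes(x = .data[[xnm]], y = .data$value))
  if (length(sweeps) > 1) {
    gnm <- resolve_sweep_fields(names(sweeps)[[1]])[1]
    p <- p + ggplot2::aes(colour = factor(.data[[gnm]]),
                          group = factor(.data[[gnm]])) +
      ggplot2::labs(colour = gnm)
  }
  p <- p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = xnm, y = "value")
  if (length(unique(object$quantity)) > 1) {
    p <- p + ggplot2::facet_wrap(~quantity, scales = "free_y")
  }
  p
}

#' @rdname autoplot.epi_grid_result
#' @method plot epi_grid_result
#' @export
plot.epi_grid_result <- function(x, ...) print(autoplot.epi_grid_result(x))

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
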