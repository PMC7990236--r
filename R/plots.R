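#' Plot modeled concentration time series
#'
#' @param sim A `watershed_sim` object.
#' @param compartment Compartment to plot (default `"stream"`).
#' @param subwatersheds Optional subset of sub-watershed ids.
#' @return A ggplot object: concentration (uM) over time, faceted by
#'   species (rows) and sub-watershed (columns).
#' @export
plot_concentrations <- function(sim, compartment = "stream",
                                subwatersheds = NULL) {
  dat <- tidy(sim) %>%
    filter(.data$compartment == .env$compartment)
  if (!is.null(subwatersheds)) {
    dat <- dat %>% filter(.data$subwatershed %in% subwatersheds)
  }
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$timestamp, y = .data$uM)
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$species),
      cols = ggplot2::vars(.data$subwatershed),
      scales = "free_y"
    ) +
    ggplot2::labs(
      x = NULL, y = "concentration (µM)",
      title = paste0(
        compartment, " nitrogen, scenario ", sim$scenario$name
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an annual source/sink budget
#'
#' @param budget A budget tibble from [annual_budget()].
#' @return A ggplot object: percentage shares of the source and sink
#'   categories, side by side.
#' @export
plot_budget <- function(budget) {
  ggplot2::ggplot(
    budget,
    ggplot2::aes(
      x = .data$category, y = .data$share_pct, fill = .data$flux
    )
  ) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(
      x = NULL, y = "share of annual total (%)",
      title = paste0(
        "Water year ", budget$water_year[1], ", scenario ",
        budget$scenario[1]
      ),
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_concentrations
#' @param object A `watershed_sim` object.
#' @param ... Passed to [plot_concentrations()].
#' @method autoplot watershed_sim
#' @export
autoplot.watershed_sim <- function(object, ...) {
  plot_concentrations(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
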