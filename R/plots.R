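#' Plot a simulated trajectory
#'
#' Faceted concentration-vs-time panels, by default the six routinely
#' measured species.
#'
#' @param object An `abe_trajectory`.
#' @param species Species to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abe_trajectory
#' @export
autoplot.abe_trajectory <- function(object,
                                    species = c("G", "X", "Ac", "Buty",
                                                "An", "BuOH"), ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[c("time_h", species)],
                              -"time_h", names_to = "species",
                              values_to = "mM")
  long$species <- factor(long$species, levels = species)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$mM)) +
    ggplot2::geom_line(colour = "#2c6fbb") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (mM)")
}

#' @rdname autoplot.abe_trajectory
#' @export
plot_trajectory <- function(object, ...) autoplot(object, ...)

#' Plot a selectivity / production response surface
#'
#' Raster of an endpoint quantity over the glucose x NADH plane (one acetate
#' level at a time).
#'
#' @param object An `abe_sweep`.
#' @param quantity Column to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abe_sweep
#' @export
autoplot.abe_sweep <- function(object, quantity = "selectivity", ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$glucose_mM, .data$nadh_mM,
                               fill = .data[[quantity]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "initial glucose (mM)", y = "initial NADH (mM)",
                  fill = quantity)
}

#' @rdname autoplot.abe_sweep
#' @export
plot_sweep <- function(object, ...) autoplot(object, ...)

#' Plot a sensitivity ranking
#'
#' Horizontal bars of the ranked sensitivity magnitudes per species and
#' evaluation time.
#'
#' @param ranking Output of [sensitivity_ranking()].
#' @return A ggplot.
#' @export
plot_sensitivity <- function(ranking) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(.data$S_max_abs,
                               stats::reorder(.data$parameter,
                                              .data$S_max_abs))) +
    ggplot2::geom_col(fill = "#2c6fbb") +
    ggplot2::facet_grid(tau_h ~ species, scales = "free") +
    ggplot2::labs(x = "|S| (%)", y = NULL)
}
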