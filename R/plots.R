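# ggplot2 views of the three result types. Colours follow the customary
# phase-diagram reading: blue for cooperative dominance, pink/red for the
# coexistence pair.

outcome_palette <- c(
  cooperative_dominance = "#3B6FB6",
  cooperative_coexistence = "#E8A0BF",
  noncooperative_coexistence = "#C0392B",
  noncooperative_dominance = "#7B241C",
  bistability = "#F1C40F",
  no_fishing = "grey70",
  degenerate = "grey40")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Phase diagram of game outcomes
#'
#' @param object An `outcome_sweep` from [sweep_scenario()].
#' @param ... Unused.
#' @return A ggplot object: outcome label over the (r, B') plane.
#' @export
autoplot.outcome_sweep <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$B_prime,
                               fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = outcome_palette, drop = TRUE,
                               name = "outcome") +
    ggplot2::labs(x = "stock growth rate r",
                  y = "relative stock size B'") +
    ggplot2::theme_minimal()
}

#' Equilibrium cooperator frequency against growth rate
#'
#' @param object A `frequency_curves` table from [frequency_curves()].
#' @param ... Unused.
#' @return A ggplot object: one line per relative stock size.
#' @export
autoplot.frequency_curves <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$x_C_eq,
                               colour = .data$B_prime,
                               group = .data$B_prime)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_colour_viridis_c(name = "B'") +
    ggplot2::labs(x = "stock growth rate r",
                  y = "equilibrium cooperator frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Replicator trajectory of both strategies
#'
#' @param object A `replicator_trajectory` from [replicator_integrate()]
#'   or [run_invasion()].
#' @param ... Unused.
#' @return A ggplot object: cooperator and cheater frequency over
#'   generations.
#' @export
autoplot.replicator_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("x_C", "x_N"),
                              names_to = "strategy",
                              values_to = "frequency")
  long$strategy <- ifelse(long$strategy == "x_C", "cooperators",
                          "non-cooperators")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$frequency,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(cooperators = "#3B6FB6", `non-cooperators` = "#C0392B")) +
    ggplot2::labs(x = "generation (fishing season)", y = "frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
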