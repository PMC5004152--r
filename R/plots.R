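#' Plot fitness and connectivity trajectories of a scenario run
#'
#' Best fitness and best-network active fraction per generation, one line per
#' replicate.
#'
#' @param object An `evo_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.evo_run <- function(object, ...) {
  df <- object$trajectory |>
    tidyr::pivot_longer(c("best_fitness", "active_fraction"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$value,
                                   group = .data$replicate,
                                   colour = factor(.data$replicate))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL, colour = "replicate",
                  title = paste0("Scenario '", object$config$name, "'")) +
    ggplot2::theme_minimal()
}

#' Plot fitness trajectories of a duplication-growth run
#'
#' Best fitness per generation, coloured by module count, faceted by
#' replicate. Lineage generations are plotted on their own within-stage axis,
#' so the dip after each duplication event is visible at the left edge of
#' each colour.
#'
#' @param object A `duplication_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.duplication_run <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness,
                               colour = factor(.data$module_count))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~replicate) +
    ggplot2::labs(x = "generation within lineage", y = "best fitness",
                  colour = "modules") +
    ggplot2::theme_minimal()
}

#' Plot evolved versus null modularity intervals
#'
#' Mean Q with percentile 95% intervals for evolved networks and their
#' degree-preserving nulls, by partitioning method.
#'
#' @param object A `modularity_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.modularity_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$method, y = .data$mean_q,
                               colour = .data$network)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "modularity Q", colour = NULL) +
    ggplot2::theme_minimal()
}
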