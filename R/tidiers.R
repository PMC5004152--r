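#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a scenario run into its per-generation trajectory
#'
#' @param x An `evo_run`.
#' @param ... Unused.
#' @return Tibble with columns replicate, generation, best_fitness,
#'   mean_fitness, active_count, active_fraction, mean_active_fraction.
#' @exportS3Method generics::tidy
tidy.evo_run <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a scenario run
#'
#' @param x An `evo_run`.
#' @param ... Unused.
#' @return One-row tibble: scenario, n_replicates, generations, mean and sd
#'   of final best fitness, and mean final active count and fraction of the
#'   best network per replicate.
#' @exportS3Method generics::glance
glance.evo_run <- function(x, ...) {
  fr <- vapply(x$best_genomes, function(g) mean(g$m_ih), numeric(1))
  cnt <- vapply(x$best_genomes, function(g) sum(g$m_ih), numeric(1))
  tibble::tibble(
    scenario = x$config$name,
    n_replicates = x$config$n_replicates,
    generations = x$config$generations,
    mean_final_fitness = mean(x$final_fitness),
    sd_final_fitness = stats::sd(x$final_fitness),
    mean_active_count = mean(cnt),
    mean_active_fraction = mean(fr))
}

#' Tidy a duplication run into its per-lineage trajectory
#'
#' @param x A `duplication_run`.
#' @param ... Unused.
#' @return Tibble with replicate, stage, module_count, generation (within
#'   lineage) and fitness columns.
#' @exportS3Method generics::tidy
tidy.duplication_run <- function(x, ...) {
  x$trajectory
}

#' Per-branch summary of a duplication run
#'
#' @param x A `duplication_run`.
#' @param ... Unused.
#' @return Tibble with one row per module count: mean parent fitness at
#'   branch, mean child start fitness, mean dip depth and mean recovery
#'   generation across replicates.
#' @exportS3Method generics::glance
glance.duplication_run <- function(x, ...) {
  x$branch_summary |>
    dplyr::group_by(.data$module_count, .data$child_module_count) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_parent_fitness = mean(.data$parent_fitness_at_branch),
      mean_child_start_fitness = mean(.data$child_start_fitness),
      mean_dip_depth = mean(.data$dip_depth),
      mean_recovery_generation = mean(.data$recovery_generation, na.rm = TRUE),
      n_recovered = sum(!is.na(.data$recovery_generation)),
      .groups = "drop")
}

#' Tidy a modularity report into its per-fit scores
#'
#' @param x A `modularity_report`.
#' @param ... Unused.
#' @return Tibble with genome, network (evolved/null), method, q and
#'   faction_cost per fitted partition.
#' @exportS3Method generics::tidy
tidy.modularity_report <- function(x, ...) {
  x$scores
}

#' Interval summary of a modularity report
#'
#' @param x A `modularity_report`.
#' @param ... Unused.
#' @return Tibble with mean Q and percentile 95% CI per method and network
#'   class.
#' @exportS3Method generics::glance
glance.modularity_report <- function(x, ...) {
  x$summary
}

#' Tidy a partition into a node table
#'
#' @param x A `partition`.
#' @param ... Unused.
#' @return Tibble with columns node and group.
#' @exportS3Method generics::tidy
tidy.partition <- function(x, ...) {
  tibble::tibble(node = seq_along(x$labels), group = x$labels)
}
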