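#' Evolved-versus-null modularity report
#'
#' The headline comparison: for each evolved genome, the association matrix
#' of its connection mask is partitioned with Tabu faction search and (by
#' default) also with Girvan-Newman, and the same scoring is applied to
#' `n_null` degree-preserving random rewirings of that mask. Overlapping
#' evolved and null confidence intervals mean the evolved wiring is no more
#' modular than expected at random for its degree sequence.
#'
#' @param genomes List of `network_genome` objects (or logical masks), e.g.
#'   `run$best_genomes` from [run_scenario()].
#' @param n_null Number of degree-preserving nulls per genome (>= 2).
#' @param n_groups Number of groups assumed by the partitioners (default 2).
#' @param seed Integer seed; per-genome and per-null sub-seeds derive from it.
#' @param methods Any of `"tabu"`, `"girvan_newman"`.
#' @param tabu A [tabu_params()] template (its seed is replaced per fit).
#' @return A `modularity_report`: list with `scores` (tibble: genome, network
#'   = evolved/null, null_id, method, q, faction_cost), `summary` (tibble:
#'   method, network, n, mean_q, ci_lower, ci_upper — percentile 95% CI of
#'   the score distribution), and the call parameters.
#' @export
modularity_report <- function(genomes, n_null = 100L, n_groups = 2L,
                              seed = 1L,
                              methods = c("tabu", "girvan_newman"),
                              tabu = tabu_params()) {
  if (inherits(genomes, "network_genome")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1)
  if (n_null < 2) stop("`n_null` must be at least 2 to form an interval",
                       call. = FALSE)
  methods <- match.arg(methods, several.ok = TRUE)
  masks <- lapply(genomes, function(g) {
    if (inherits(g, "network_genome")) g$m_ih else g
  })
  genome_seeds <- derive_seeds(seed, length(masks))
  rows <- list()
  for (i in seq_along(masks)) {
    sub <- derive_seeds(genome_seeds[i], n_null + 1L)
    # one fitting seed per genome: identical masks always score identically,
    # so a mask whose null rewiring is forced (e.g. a full mask) gets exactly
    # its own score. Null masks themselves vary through their own seeds.
    fit_seed <- sub[1L]
    rows[[length(rows) + 1L]] <- score_mask(masks[[i]], i, NA_integer_,
                                            "evolved", methods, n_groups,
                                            tabu, fit_seed)
    for (k in seq_len(n_null)) {
      nm <- degree_preserving_null(masks[[i]], seed = sub[1L + k])
      rows[[length(rows) + 1L]] <- score_mask(nm, i, k, "null", methods,
                                              n_groups, tabu, fit_seed)
    }
  }
  scores <- dplyr::bind_rows(rows)
  summary <- scores |>
    dplyr::group_by(.data$method, .data$network) |>
    dplyr::summarise(n = dplyr::n(), mean_q = mean(.data$q),
                     ci_lower = stats::quantile(.data$q, 0.025, names = FALSE),
                     ci_upper = stats::quantile(.data$q, 0.975, names = FALSE),
                     mean_cost = mean(.data$faction_cost),
                     .groups = "drop")
  structure(list(scores = scores, summary = summary, n_null = n_null,
                 n_groups = as.integer(n_groups), methods = methods,
                 seed = as.integer(seed)),
            class = "modularity_report")
}

score_mask <- function(mask, genome_id, null_id, network, methods, n_groups,
                       tabu, seed) {
  am <- association_matrix(mask)
  out <- list()
  if ("tabu" %in% methods) {
    tp <- tabu
    tp$seed <- seed
    p <- tabu_factions(am, n_groups, tp)
    out[[length(out) + 1L]] <- tibble::tibble(
      genome = genome_id, network = network, null_id = null_id,
      method = "tabu", q = p$q, faction_cost = p$faction_cost)
  }
  if ("girvan_newman" %in% methods) {
    p <- girvan_newman_partition(am, n_groups)
    out[[length(out) + 1L]] <- tibble::tibble(
      genome = genome_id, network = network, null_id = null_id,
      method = "girvan_newman", q = p$q, faction_cost = p$faction_cost)
  }
  dplyr::bind_rows(out)
}

#' Do the evolved and null modularity intervals overlap?
#'
#' Convenience accessor on a [modularity_report()]: for each method, checks
#' whether the 95% interval of evolved Q overlaps the 95% interval of the
#' null Q distribution.
#'
#' @param report A `modularity_report`.
#' @return Tibble with columns `method` and `overlap` (logical).
#' @export
ci_overlap <- function(report) {
  stopifnot(inherits(report, "modularity_report"))
  report$summary |>
    tidyr::pivot_wider(id_cols = "method", names_from = "network",
                       values_from = c("ci_lower", "ci_upper")) |>
    dplyr::mutate(overlap = .data$ci_lower_evolved <= .data$ci_upper_null &
                    .data$ci_lower_null <= .data$ci_upper_evolved) |>
    dplyr::select("method", "overlap")
}

#' @export
print.modularity_report <- function(x, ...) {
  cat("<modularity_report> ", length(unique(x$scores$genome)),
      " genome(s), ", x$n_null, " nulls each, ", x$n_groups, " groups\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' Write the outputs of a run to a directory
#'
#' Writes `trajectory.csv`, per-replicate best-genome JSONs (plus edge lists)
#' under `genomes/`, and a `manifest.json` capturing the fully resolved
#' configuration and all replicate seeds.
#'
#' @param run An `evo_run` or `duplication_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, c("evo_run", "duplication_run")))
  dir.create(file.path(dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(run$trajectory, file.path(dir, "trajectory.csv"))
  genomes <- if (inherits(run, "evo_run")) run$best_genomes else run$final_genomes
  for (r in seq_along(genomes)) {
    write_genome(genomes[[r]],
                 file.path(dir, "genomes", sprintf("replicate_%03d.json", r)))
    write_edge_list(genomes[[r]],
                    file.path(dir, "genomes",
                              sprintf("replicate_%03d_edges.csv", r)))
  }
  if (inherits(run, "duplication_run") && nrow(run$branch_summary)) {
    readr::write_csv(run$branch_summary,
                     file.path(dir, "branch_summary.csv"))
  }
  manifest <- list(config = unclass_deep(run$config),
                   replicate_seeds = run$replicate_seeds,
                   package_version = as.character(utils::packageVersion("modnet")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Read the best genomes written by [write_run()]
#'
#' @param dir Directory containing a `genomes/` subdirectory.
#' @return List of `network_genome` objects in replicate order.
#' @export
read_run_genomes <- function(dir) {
  files <- sort(list.files(file.path(dir, "genomes"),
                           pattern = "^replicate_\\d+\\.json$",
                           full.names = TRUE))
  if (!length(files)) stop("no genome JSONs found under ", dir, call. = FALSE)
  lapply(files, read_genome)
}
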