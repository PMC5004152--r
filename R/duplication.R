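#' Duplicate a network's entire architecture and weights
#'
#' Whole-module duplication: the input-to-hidden weight matrix and connection
#' mask become block-diagonal with two identical copies (no cross-copy
#' connections), hidden biases are duplicated, and the hidden-to-output
#' weight vector is concatenated with a copy of itself. The single output
#' node (and its bias) is shared, so the network grows from `I-H-1` to
#' `2I-2H-1`. Weights are copied exactly, with no rescaling of the output
#' drive.
#'
#' @param genome A `network_genome`.
#' @return The doubled `network_genome`.
#' @examples
#' g <- init_genome(8, 4, seed = 1)
#' d <- duplicate_genome(g)
#' dim(d$w_ih)                      # 16 x 8
#' active_stats(d)$count == 2 * active_stats(g)$count
#' @export
duplicate_genome <- function(genome) {
  stopifnot(inherits(genome, "network_genome"))
  I <- nrow(genome$w_ih); H <- ncol(genome$w_ih)
  w <- matrix(0, 2L * I, 2L * H)
  m <- matrix(FALSE, 2L * I, 2L * H)
  w[seq_len(I), seq_len(H)] <- genome$w_ih
  w[I + seq_len(I), H + seq_len(H)] <- genome$w_ih
  m[seq_len(I), seq_len(H)] <- genome$m_ih
  m[I + seq_len(I), H + seq_len(H)] <- genome$m_ih
  new_genome(w, m, w_ho = c(genome$w_ho, genome$w_ho),
             b_h = c(genome$b_h, genome$b_h), b_o = genome$b_o,
             beta = genome$beta)
}

#' Configure a duplication-growth experiment
#'
#' The experiment starts from a fully connected 8-4-1 network on one input
#' block and grows by whole-architecture duplication: each lineage evolves
#' weights only (no connective mutation); after `branch_generation`
#' generations every individual in the population is duplicated and the input
#' set gains a fresh block, founding the next (doubled) lineage, while the
#' parent lineage continues to `stage_generations` for comparison. Canonical
#' settings: 10000 generations per stage, branching at 1000, module sequence
#' 1, 2, 4, 8, 16, per-weight mutation probability 1/1000 with sd 1, 20
#' replicates.
#'
#' @param stage_generations Generations each lineage is run for.
#' @param branch_generation Generation at which the next lineage branches.
#' @param module_sequence Module counts of successive stages; each entry must
#'   double the previous one.
#' @param weight_regime A [weight_regime()].
#' @param pop_size,n_parents,n_clones GA shape.
#' @param n_accept Accept-subset size (unchanged across duplications).
#' @param redraw_accept Redraw the accept subset when a new input block is
#'   acquired? Default `FALSE` (the target rows are kept).
#' @param n_replicates,master_seed,record_every As in [scenario_config()].
#' @return A `duplication_config` list.
#' @export
duplication_config <- function(stage_generations = 10000L,
                               branch_generation = 1000L,
                               module_sequence = c(1L, 2L, 4L, 8L, 16L),
                               weight_regime = modnet::weight_regime(
                                 "per_weight_prob", prob = 1 / 1000, sd = 1),
                               pop_size = 50L, n_parents = 10L,
                               n_clones = 5L, n_accept = 100L,
                               redraw_accept = FALSE, n_replicates = 20L,
                               master_seed = 1L, record_every = 1L) {
  stopifnot(branch_generation < stage_generations,
            length(module_sequence) >= 1, module_sequence[1] >= 1)
  if (length(module_sequence) > 1 &&
      any(diff(log2(module_sequence)) != 1)) {
    stop("`module_sequence` must double at each stage", call. = FALSE)
  }
  structure(
    list(stage_generations = as.integer(stage_generations),
         branch_generation = as.integer(branch_generation),
         module_sequence = as.integer(module_sequence),
         weight_regime = weight_regime, pop_size = as.integer(pop_size),
         n_parents = as.integer(n_parents), n_clones = as.integer(n_clones),
         n_accept = as.integer(n_accept),
         redraw_accept = isTRUE(redraw_accept),
         n_replicates = as.integer(n_replicates),
         master_seed = as.integer(master_seed),
         record_every = as.integer(record_every)),
    class = "duplication_config"
  )
}

stage_scenario_config <- function(config, module_count, generations) {
  scenario_config(
    name = paste0("duplication_m", module_count),
    n_blocks = as.integer(module_count),
    weight_regime = config$weight_regime,
    connective_regime = connective_regime("none"),
    pop_size = config$pop_size, n_parents = config$n_parents,
    n_clones = config$n_clones, generations = as.integer(generations),
    n_replicates = 1L, n_accept = config$n_accept,
    master_seed = config$master_seed, record_every = config$record_every)
}

#' Run a duplication-growth experiment
#'
#' For each replicate, evolves the module sequence described in
#' [duplication_config()]. Each stage's lineage is recorded for its full
#' `stage_generations`; the next lineage branches off at `branch_generation`
#' by duplicating every individual and extending the input set with a fresh
#' block, and then evolves with an independent random stream so parent/child
#' comparisons are paired within replicate.
#'
#' @param config A [duplication_config()].
#' @param verbose Progress-line interval in generations (0 = silent).
#' @return A `duplication_run` object: `trajectory` (tibble with replicate,
#'   stage, module_count, generation (within lineage), best_fitness,
#'   mean_fitness), `branch_summary` (tibble with, per replicate and branch
#'   event: parent module count, parent fitness at branch, child fitness at
#'   its first generation, dip depth, and recovery generation — the first
#'   child generation whose best fitness reaches the parent's branch-point
#'   fitness), `final_genomes` (best final individual of the last stage per
#'   replicate) and `config`.
#' @export
run_duplication_experiment <- function(config, verbose = 0L) {
  stopifnot(inherits(config, "duplication_config"))
  rep_seeds <- derive_seeds(config$master_seed, config$n_replicates)
  reps <- lapply(seq_len(config$n_replicates), function(r) {
    run_duplication_replicate(config, rep_seeds[r], r, verbose)
  })
  structure(
    list(config = config,
         trajectory = dplyr::bind_rows(lapply(reps, `[[`, "trajectory")),
         branch_summary = dplyr::bind_rows(lapply(reps, `[[`, "summary")),
         final_genomes = lapply(reps, `[[`, "final_genome"),
         replicate_seeds = rep_seeds),
    class = "duplication_run"
  )
}

run_duplication_replicate <- function(config, seed, replicate_id,
                                      verbose = 0L) {
  n_stages <- length(config$module_sequence)
  # seeds: input set, then per stage: pre-branch, parent continuation,
  # duplication/extension, child stream
  seeds <- derive_seeds(seed, 1L + 4L * n_stages)
  cfg0 <- stage_scenario_config(config, config$module_sequence[1], 1L)
  inputs <- build_input_set(cfg0, seeds[1L])
  init_seeds <- derive_seeds(seeds[2L], config$pop_size)
  population <- init_population(cfg0, init_seeds)
  traj <- list()
  summ <- list()
  final_genome <- NULL
  for (k in seq_len(n_stages)) {
    m <- config$module_sequence[k]
    s <- seeds[1L + 4L * (k - 1L) + seq_len(4L)]
    branches <- k < n_stages
    pre_gens <- if (branches) config$branch_generation else config$stage_generations
    cfg_pre <- stage_scenario_config(config, m, pre_gens)
    pre <- run_one_replicate(cfg_pre, s[1L], replicate_id = replicate_id,
                             verbose = verbose, inputs = inputs,
                             population = population)
    stage_traj <- pre$trajectory
    if (branches) {
      branch_fitness <- pre$best_fitness
      # child founders: every individual duplicated; the input set doubles
      # too (one fresh block per newly created module)
      child_pop <- lapply(pre$population, duplicate_genome)
      child_inputs <- inputs
      block_seeds <- derive_seeds(s[3L], inputs$n_blocks)
      for (bs in block_seeds) {
        child_inputs <- extend_input_set(child_inputs, seed = bs,
                                         redraw_accept = config$redraw_accept)
      }
      # parent lineage continues on its own stream
      cfg_cont <- stage_scenario_config(
        config, m, config$stage_generations - config$branch_generation)
      cont <- run_one_replicate(cfg_cont, s[2L], replicate_id = replicate_id,
                                verbose = verbose, inputs = inputs,
                                population = pre$population,
                                generation_offset = config$branch_generation)
      stage_traj <- dplyr::bind_rows(stage_traj, cont$trajectory)
      population <- child_pop
      inputs <- child_inputs
      summ[[k]] <- tibble::tibble(
        replicate = replicate_id, stage = k, module_count = m,
        child_module_count = 2L * m,
        branch_generation = config$branch_generation,
        parent_fitness_at_branch = branch_fitness)
    } else {
      final_genome <- pre$best_genome
    }
    traj[[k]] <- dplyr::mutate(stage_traj, stage = k, module_count = m,
                               .after = "replicate")
  }
  traj <- dplyr::bind_rows(traj)
  summ <- dplyr::bind_rows(summ)
  # dip and recovery: compare each child lineage with its parent's
  # branch-point fitness
  if (nrow(summ)) {
    summ <- dplyr::bind_rows(lapply(seq_len(nrow(summ)), function(i) {
      row <- summ[i, ]
      child <- dplyr::filter(traj, .data$stage == row$stage + 1L)
      fb <- row$parent_fitness_at_branch
      child_start <- child$best_fitness[1L]
      reached <- which(child$best_fitness >= fb)
      dplyr::mutate(
        row,
        child_start_fitness = child_start,
        dip_depth = fb - child_start,
        recovery_generation = if (length(reached)) {
          child$generation[reached[1L]]
        } else NA_integer_)
    }))
  }
  list(trajectory = traj, summary = summ, final_genome = final_genome)
}

#' @export
print.duplication_run <- function(x, ...) {
  cat("<duplication_run> module sequence ",
      paste(x$config$module_sequence, collapse = " -> "), ", ",
      x$config$n_replicates, " replicate(s)\n", sep = "")
  if (nrow(x$branch_summary)) {
    s <- dplyr::summarise(
      dplyr::group_by(x$branch_summary, .data$module_count),
      mean_dip = mean(.data$dip_depth),
      mean_recovery = mean(.data$recovery_generation, na.rm = TRUE))
    print(s)
  }
  invisible(x)
}
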