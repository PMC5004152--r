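#' Weight-mutation regimes
#'
#' Two regimes are used across the scenario presets: `every_weight`, in which
#' every weight and bias is perturbed each generation by an additive
#' Normal(0, sd) draw (sd 0.25 in the canonical setting), and
#' `per_weight_prob`, in which each parameter mutates independently with a
#' small probability (1/1000 in the low-rate setting) by a larger
#' Normal(0, sd = 1) step. Inactive connections keep mutating: a switched-off
#' connection drifts neutrally and may return with a changed weight.
#'
#' @param mode `"every_weight"` or `"per_weight_prob"`.
#' @param prob Per-parameter mutation probability (forced to 1 for
#'   `every_weight`).
#' @param sd Standard deviation of the additive normal perturbation.
#' @return A `weight_regime` list.
#' @export
weight_regime <- function(mode = c("every_weight", "per_weight_prob"),
                          prob = 1, sd = 0.25) {
  mode <- match.arg(mode)
  if (mode == "every_weight") prob <- 1
  stopifnot(prob > 0, prob <= 1, sd >= 0)
  structure(list(mode = mode, prob = prob, sd = sd, mean = 0),
            class = "weight_regime")
}

#' Connective-mutation regimes
#'
#' Controls how the input-to-hidden connection mask evolves. `symmetric`
#' flips each connection's on/off state independently with probability
#' `flip_prob` per generation (0.001 canonically); `irreversible_loss` allows
#' only active-to-inactive transitions at the same probability; `none` keeps
#' the mask fixed (weight-only evolution on a static architecture).
#'
#' @param mode `"none"`, `"symmetric"` or `"irreversible_loss"`.
#' @param flip_prob Per-connection transition probability per generation.
#' @return A `connective_regime` list.
#' @export
connective_regime <- function(mode = c("none", "symmetric",
                                       "irreversible_loss"),
                              flip_prob = 0.001) {
  mode <- match.arg(mode)
  stopifnot(flip_prob >= 0, flip_prob < 1)
  structure(list(mode = mode, flip_prob = flip_prob),
            class = "connective_regime")
}

#' Mutate the weights and biases of a genome
#'
#' Perturbs every parameter of the genome (input-to-hidden weights including
#' those of inactive connections, hidden-to-output weights, hidden biases and
#' the output bias) with the regime's per-parameter probability by adding a
#' Normal(0, sd) draw. The connection mask is untouched.
#'
#' @param genome A `network_genome`.
#' @param regime A [weight_regime()].
#' @return The mutated `network_genome`.
#' @export
mutate_weights <- function(genome, regime) {
  stopifnot(inherits(genome, "network_genome"),
            inherits(regime, "weight_regime"))
  if (regime$sd == 0) return(genome)
  genome$w_ih <- perturb(genome$w_ih, regime)
  genome$w_ho <- perturb(genome$w_ho, regime)
  genome$b_h <- perturb(genome$b_h, regime)
  genome$b_o <- perturb(genome$b_o, regime)
  genome
}

perturb <- function(x, regime) {
  n <- length(x)
  if (regime$prob >= 1) {
    return(x + stats::rnorm(n, 0, regime$sd))
  }
  k <- stats::rbinom(1L, n, regime$prob)
  if (k > 0L) {
    idx <- sample.int(n, k)
    x[idx] <- x[idx] + stats::rnorm(k, 0, regime$sd)
  }
  x
}

#' Mutate the connection mask of a genome
#'
#' Applies one generation of connective mutation: under `symmetric`, each
#' mask entry flips state independently with probability `flip_prob`; under
#' `irreversible_loss`, only active connections can change (to inactive) at
#' that probability; under `none` the mask is returned unchanged. Weights are
#' untouched.
#'
#' @param genome A `network_genome`.
#' @param regime A [connective_regime()].
#' @return The mutated `network_genome`.
#' @export
mutate_connections <- function(genome, regime) {
  stopifnot(inherits(genome, "network_genome"),
            inherits(regime, "connective_regime"))
  if (regime$mode == "none" || regime$flip_prob == 0) return(genome)
  m <- genome$m_ih
  if (regime$mode == "symmetric") {
    k <- stats::rbinom(1L, length(m), regime$flip_prob)
    if (k > 0L) {
      idx <- sample.int(length(m), k)
      m[idx] <- !m[idx]
    }
  } else { # irreversible_loss
    active <- which(m)
    if (length(active)) {
      k <- stats::rbinom(1L, length(active), regime$flip_prob)
      if (k > 0L) m[active[sample.int(length(active), k)]] <- FALSE
    }
  }
  genome$m_ih <- m
  genome
}

#' Truncation selection with cloning
#'
#' Ranks the population by fitness (ties broken by stable input order), keeps
#' the top `n_parents`, and emits `n_clones` unmutated copies of each, so the
#' offspring population has exactly `pop_size = n_parents * n_clones`
#' members. No elitism: every offspring is subsequently mutated.
#'
#' @param population List of `network_genome` objects.
#' @param fitnesses Numeric vector, one fitness per genome.
#' @param n_parents Number of top performers retained (default 10).
#' @param n_clones Copies per parent (default 5).
#' @return List of `n_parents * n_clones` genomes.
#' @export
select_reproduce <- function(population, fitnesses, n_parents = 10L,
                             n_clones = 5L) {
  if (length(population) != length(fitnesses)) {
    stop("`population` and `fitnesses` lengths differ", call. = FALSE)
  }
  if (length(population) != n_parents * n_clones) {
    stop("population size (", length(population), ") must equal ",
         "n_parents * n_clones (", n_parents * n_clones, ")", call. = FALSE)
  }
  ord <- order(-fitnesses, seq_along(fitnesses))
  top <- ord[seq_len(n_parents)]
  population[rep(top, each = n_clones)]
}

#' Configure an evolutionary scenario
#'
#' Bundles all parameters of one gradualistic simulation: network size, task,
#' mutation regimes, GA shape and run length. Use [scenario_preset()] for the
#' named study scenarios.
#'
#' @param name Scenario label (recorded in outputs).
#' @param n_blocks Number of 8-column input blocks; the network has
#'   `8 * n_blocks` inputs and half as many hidden nodes.
#' @param task_kind `"accept_reject"` or `"dull_intense"`.
#' @param weight_regime A [weight_regime()].
#' @param connective_regime A [connective_regime()].
#' @param start_arch Initial architecture kind: `"fcnmn"`, `"empty"` or
#'   `"pmn"` (the latter with `connective_regime("none")` gives the fixed
#'   perfectly modular control).
#' @param pop_size,n_parents,n_clones GA shape (50 = 10 x 5 canonically).
#' @param generations Number of generations to run.
#' @param n_replicates Independent replicates, each with its own input set.
#' @param n_accept Accept-subset size (accept/reject task).
#' @param n_dull Dulled-row count (dull/intense task).
#' @param selection If `FALSE`, selection is disabled: every individual
#'   reproduces itself once per generation (pure mutation-drift; used to
#'   check the neutral closed form for connection-mask drift). Fitness is
#'   then not evaluated, which is distributionally equivalent because flat
#'   fitness makes selection independent of the outputs.
#' @param master_seed Master seed; all replicate randomness derives from it.
#' @param record_every Record trajectory statistics every this many
#'   generations (generation 1 and the final generation are always recorded).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(name = "custom", n_blocks = 12L,
                            task_kind = c("accept_reject", "dull_intense"),
                            weight_regime = modnet::weight_regime(),
                            connective_regime = modnet::connective_regime("symmetric"),
                            start_arch = c("fcnmn", "empty", "pmn"),
                            pop_size = 50L, n_parents = 10L, n_clones = 5L,
                            generations = 10000L, n_replicates = 20L,
                            n_accept = 100L, n_dull = 140L,
                            selection = TRUE, master_seed = 1L,
                            record_every = 1L) {
  task_kind <- match.arg(task_kind)
  start_arch <- match.arg(start_arch)
  if (pop_size != n_parents * n_clones) {
    stop("`pop_size` must equal `n_parents * n_clones`", call. = FALSE)
  }
  n_inputs <- 8L * as.integer(n_blocks)
  structure(
    list(name = name, n_blocks = as.integer(n_blocks), n_inputs = n_inputs,
         n_hidden = n_inputs %/% 2L, task_kind = task_kind,
         weight_regime = weight_regime, connective_regime = connective_regime,
         start_arch = start_arch, pop_size = as.integer(pop_size),
         n_parents = as.integer(n_parents), n_clones = as.integer(n_clones),
         generations = as.integer(generations),
         n_replicates = as.integer(n_replicates),
         n_accept = as.integer(n_accept), n_dull = as.integer(n_dull),
         selection = isTRUE(selection),
         master_seed = as.integer(master_seed),
         record_every = as.integer(record_every)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$name, ": ", x$n_inputs, "-", x$n_hidden,
      "-1, ", x$task_kind, "\n  weights: ", x$weight_regime$mode,
      " (p=", x$weight_regime$prob, ", sd=", x$weight_regime$sd,
      "); connections: ", x$connective_regime$mode,
      " (p=", x$connective_regime$flip_prob, "), start ", x$start_arch,
      "\n  GA: pop ", x$pop_size, " = top ", x$n_parents, " x ", x$n_clones,
      " clones; ", x$generations, " generations x ", x$n_replicates,
      " replicates\n", sep = "")
  invisible(x)
}

build_input_set <- function(config, seed) {
  base <- assemble_input_set(config$n_blocks, n_accept = config$n_accept,
                             seed = seed)
  if (config$task_kind == "dull_intense") {
    base <- make_dull_variant(base, n_dull = config$n_dull,
                              seed = derive_seeds(seed, 2L)[2L])
  }
  base
}

init_population <- function(config, seeds) {
  arch <- architecture_spec(config$start_arch, config$n_inputs,
                            config$n_hidden)
  lapply(seeds, function(s) {
    init_genome(config$n_inputs, config$n_hidden, arch = arch, seed = s)
  })
}

#' Run one gradualistic evolutionary scenario
#'
#' For each replicate: assemble a fresh input set, initialise `pop_size`
#' genomes from the configured starting architecture, then iterate the
#' generation loop `evaluate -> select/clone -> mutate weights -> mutate
#' connections` for `generations` generations. The trajectory records, per
#' recorded generation, the best and mean fitness of the population entering
#' selection and the active-connection statistics of the best individual
#' (plus the population-mean active fraction). The run is fully deterministic
#' given `master_seed`.
#'
#' @param config A [scenario_config()] (or preset name accepted by
#'   [scenario_preset()]).
#' @param verbose Print a progress line every `verbose` generations
#'   (0 = silent).
#' @return An `evo_run` object: list with `config`, `trajectory` (tibble with
#'   columns replicate, generation, best_fitness, mean_fitness, active_count,
#'   active_fraction, mean_active_fraction), `final_populations` (list per
#'   replicate), `best_genomes` (highest-fitness final individual per
#'   replicate) and `replicate_seeds`.
#' @examples
#' cfg <- scenario_config("demo", n_blocks = 1, generations = 5,
#'                        n_replicates = 1, master_seed = 1)
#' run <- run_scenario(cfg)
#' tidy(run)
#' @export
run_scenario <- function(config, verbose = 0L) {
  if (is.character(config)) config <- scenario_preset(config)
  stopifnot(inherits(config, "scenario_config"))
  rep_seeds <- derive_seeds(config$master_seed, config$n_replicates)
  reps <- lapply(seq_len(config$n_replicates), function(r) {
    run_one_replicate(config, rep_seeds[r], replicate_id = r,
                      verbose = verbose)
  })
  traj <- dplyr::bind_rows(lapply(reps, `[[`, "trajectory"))
  structure(
    list(config = config, trajectory = traj,
         final_populations = lapply(reps, `[[`, "population"),
         best_genomes = lapply(reps, `[[`, "best_genome"),
         final_fitness = vapply(reps, `[[`, numeric(1), "best_fitness"),
         replicate_seeds = rep_seeds),
    class = "evo_run"
  )
}

run_one_replicate <- function(config, seed, replicate_id = 1L, verbose = 0L,
                              inputs = NULL, population = NULL,
                              generation_offset = 0L) {
  seeds <- derive_seeds(seed, 2L + config$pop_size)
  if (is.null(inputs)) inputs <- build_input_set(config, seeds[1L])
  if (is.null(population)) {
    population <- init_population(config, seeds[2L + seq_len(config$pop_size)])
  }
  gens <- config$generations
  rec_idx <- recording_points(gens, config$record_every)
  rec_flag <- logical(gens)
  rec_flag[rec_idx] <- TRUE
  n_rec <- length(rec_idx)
  rec <- list(generation = integer(n_rec), best_fitness = numeric(n_rec),
              mean_fitness = numeric(n_rec), active_count = integer(n_rec),
              active_fraction = numeric(n_rec),
              mean_active_fraction = numeric(n_rec))
  with_seed(seeds[2L], {
    k <- 0L
    best_genome <- population[[1L]]
    best_fitness <- NA_real_
    for (g in seq_len(gens)) {
      if (config$selection) {
        fit <- evaluate_population(population, inputs)
        best_i <- order(-fit, seq_along(fit))[1L]
      } else {
        fit <- rep(NA_real_, length(population))
        best_i <- 1L
      }
      if (rec_flag[g]) {
        k <- k + 1L
        st <- active_stats(population[[best_i]])
        rec$generation[k] <- g + generation_offset
        rec$best_fitness[k] <- if (config$selection) max(fit) else NA_real_
        rec$mean_fitness[k] <- if (config$selection) mean(fit) else NA_real_
        rec$active_count[k] <- st$count
        rec$active_fraction[k] <- st$fraction
        rec$mean_active_fraction[k] <- mean(
          vapply(population, function(x) mean(x$m_ih), numeric(1)))
      }
      if (verbose > 0L && g %% verbose == 0L) {
        message(sprintf("replicate %d gen %d best %.4f active %.3f",
                        replicate_id, g + generation_offset,
                        if (config$selection) max(fit) else NA,
                        mean(population[[best_i]]$m_ih)))
      }
      if (g == gens) {
        # final population is the evaluated one, before further mutation
        best_genome <- population[[best_i]]
        best_fitness <- if (config$selection) fit[best_i] else NA_real_
        break
      }
      if (config$selection) {
        population <- select_reproduce(population, fit, config$n_parents,
                                       config$n_clones)
      }
      population <- lapply(population, mutate_weights,
                           regime = config$weight_regime)
      if (config$connective_regime$mode != "none") {
        population <- lapply(population, mutate_connections,
                             regime = config$connective_regime)
      }
    }
  })
  traj <- tibble::tibble(replicate = replicate_id, !!!rec)
  list(trajectory = traj, population = population, best_genome = best_genome,
       best_fitness = best_fitness, inputs = inputs)
}

recording_points <- function(generations, record_every) {
  if (generations == 0L) return(integer(0))
  sort(unique(c(1L, seq(record_every, generations, by = record_every),
                generations)))
}

#' @export
print.evo_run <- function(x, ...) {
  cat("<evo_run> scenario '", x$config$name, "': ",
      x$config$n_replicates, " replicate(s) x ", x$config$generations,
      " generations\n", sep = "")
  if (x$config$selection) {
    cat("  final best fitness: ",
        paste(signif(x$final_fitness, 4), collapse = ", "), "\n", sep = "")
  }
  fr <- vapply(x$best_genomes, function(g) mean(g$m_ih), numeric(1))
  cat("  final best-network active fraction: ",
      paste(signif(fr, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Temporally separated structural and weight evolution
#'
#' Alternates the two mutation processes instead of interleaving them: each
#' round applies one pass of connective mutation to every network in the
#' population, then freezes the masks and runs an inner weight-only GA for
#' `inner_generations` generations. This mimics structural mutation followed
#' by within-generation learning. The canonical setting is 400 rounds of 400
#' inner generations with flip probability 1/400 and per-weight mutation
#' probability 1/400 (sd 1), 8 replicates.
#'
#' @param rounds Number of outer structural rounds.
#' @param inner_generations Weight-only generations per round.
#' @param flip_prob Per-connection flip probability applied once per round.
#' @param weight_prob,weight_sd Inner-loop per-weight mutation probability
#'   and step size.
#' @param n_blocks,n_accept,pop_size,n_parents,n_clones,n_replicates,master_seed
#'   As in [scenario_config()].
#' @param record_every Trajectory thinning for the per-round record.
#' @return An `evo_run` whose trajectory has one row per recorded round
#'   (column `generation` counts rounds).
#' @export
run_temporal_separation <- function(rounds = 400L, inner_generations = 400L,
                                    flip_prob = 1 / 400,
                                    weight_prob = 1 / 400, weight_sd = 1,
                                    n_blocks = 12L, n_accept = 100L,
                                    pop_size = 50L, n_parents = 10L,
                                    n_clones = 5L, n_replicates = 8L,
                                    master_seed = 1L, record_every = 1L) {
  wreg <- weight_regime("per_weight_prob", prob = weight_prob, sd = weight_sd)
  creg <- connective_regime("symmetric", flip_prob = flip_prob)
  config <- scenario_config("temporal_separation", n_blocks = n_blocks,
                            weight_regime = wreg,
                            connective_regime = creg,
                            pop_size = pop_size, n_parents = n_parents,
                            n_clones = n_clones,
                            generations = as.integer(rounds),
                            n_replicates = n_replicates, n_accept = n_accept,
                            master_seed = master_seed,
                            record_every = record_every)
  rep_seeds <- derive_seeds(master_seed, n_replicates)
  reps <- lapply(seq_len(n_replicates), function(r) {
    seeds <- derive_seeds(rep_seeds[r], 2L + pop_size)
    inputs <- build_input_set(config, seeds[1L])
    population <- init_population(config, seeds[2L + seq_len(pop_size)])
    rec_idx <- recording_points(as.integer(rounds), record_every)
    rec <- list(generation = integer(0), best_fitness = numeric(0),
                mean_fitness = numeric(0), active_count = integer(0),
                active_fraction = numeric(0),
                mean_active_fraction = numeric(0))
    best_genome <- population[[1L]]
    best_fitness <- NA_real_
    with_seed(seeds[2L], {
      for (rd in seq_len(rounds)) {
        population <- lapply(population, mutate_connections, regime = creg)
        for (g in seq_len(inner_generations)) {
          fit <- evaluate_population(population, inputs)
          population <- select_reproduce(population, fit, n_parents, n_clones)
          population <- lapply(population, mutate_weights, regime = wreg)
        }
        fit <- evaluate_population(population, inputs)
        best_i <- order(-fit, seq_along(fit))[1L]
        if (rd %in% rec_idx) {
          st <- active_stats(population[[best_i]])
          rec$generation <- c(rec$generation, rd)
          rec$best_fitness <- c(rec$best_fitness, fit[best_i])
          rec$mean_fitness <- c(rec$mean_fitness, mean(fit))
          rec$active_count <- c(rec$active_count, st$count)
          rec$active_fraction <- c(rec$active_fraction, st$fraction)
          rec$mean_active_fraction <- c(
            rec$mean_active_fraction,
            mean(vapply(population, function(x) mean(x$m_ih), numeric(1))))
        }
        if (rd == rounds) {
          best_genome <- population[[best_i]]
          best_fitness <- fit[best_i]
        }
      }
    })
    list(trajectory = tibble::tibble(replicate = r, !!!rec),
         population = population, best_genome = best_genome,
         best_fitness = best_fitness)
  })
  structure(
    list(config = config,
         trajectory = dplyr::bind_rows(lapply(reps, `[[`, "trajectory")),
         final_populations = lapply(reps, `[[`, "population"),
         best_genomes = lapply(reps, `[[`, "best_genome"),
         final_fitness = vapply(reps, `[[`, numeric(1), "best_fitness"),
         replicate_seeds = rep_seeds),
    class = "evo_run"
  )
}
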