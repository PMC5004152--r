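test_that("weight mutation perturbs the documented parameter sets", {
  g <- init_genome(8, 4, seed = 1)
  # sd -> 0 limit: genome unchanged
  set.seed(1)
  expect_identical(mutate_weights(g, weight_regime("every_weight", sd = 0)), g)

  # every-weight regime perturbs all I*H + H + H + 1 parameters
  set.seed(2)
  m <- mutate_weights(g, weight_regime("every_weight", sd = 0.25))
  expect_true(all(m$w_ih != g$w_ih))
  expect_true(all(m$w_ho != g$w_ho))
  expect_true(all(m$b_h != g$b_h))
  expect_true(m$b_o != g$b_o)
  expect_identical(m$m_ih, g$m_ih)

  # inactive connections keep mutating
  g$m_ih[, ] <- FALSE
  set.seed(3)
  m2 <- mutate_weights(g, weight_regime("every_weight", sd = 0.25))
  expect_true(all(m2$w_ih != g$w_ih))
})

test_that("per-weight mutation counts follow the binomial oracle", {
  g <- init_genome(96, 48, seed = 1)
  regime <- weight_regime("per_weight_prob", prob = 1 / 1000, sd = 1)
  trials <- 2000
  set.seed(10)
  counts <- replicate(trials, {
    m <- mutate_weights(g, regime)
    sum(m$w_ih != g$w_ih)
  })
  expected <- 4608 * 1 / 1000            # 4.608 per generation
  se <- sqrt(4608 * (1 / 1000) * (1 - 1 / 1000) / trials)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("connective mutation follows its regime", {
  g <- init_genome(96, 48, seed = 2)
  set.seed(4)
  expect_identical(mutate_connections(g, connective_regime("symmetric", 0)),
                   g)
  expect_identical(mutate_connections(g, connective_regime("none", 0.5)), g)

  # symmetric flips: binomial oracle on the flip count
  trials <- 2000
  set.seed(5)
  flips <- replicate(trials, {
    m <- mutate_connections(g, connective_regime("symmetric", 0.001))
    sum(m$m_ih != g$m_ih)
  })
  se <- sqrt(4608 * 0.001 * 0.999 / trials)
  expect_lt(abs(mean(flips) - 4.608), 3 * se)

  # irreversible loss: active count is non-increasing along any call sequence
  set.seed(6)
  cur <- g
  counts <- integer(50)
  for (i in 1:50) {
    cur <- mutate_connections(cur, connective_regime("irreversible_loss", 0.05))
    counts[i] <- active_stats(cur)$count
  }
  expect_true(all(diff(c(4608L, counts)) <= 0))
  # and no connection is ever gained
  expect_true(all(cur$m_ih <= g$m_ih))
})

test_that("selection keeps the top performers with stable tie-breaking", {
  pop <- lapply(1:50, function(i) init_genome(4, 2, seed = i))
  # flat fitness: the first 10 individuals are each cloned five times
  out <- select_reproduce(pop, rep(0.5, 50))
  expect_length(out, 50)
  expect_identical(out, pop[rep(1:10, each = 5)])

  # distinct fitnesses: offspring multiset is top-10 each x5
  fit <- seq(0.01, 0.50, length.out = 50)
  out2 <- select_reproduce(pop, fit)
  expect_identical(out2, pop[rep(50:41, each = 5)])

  expect_error(select_reproduce(pop[1:20], rep(1, 20)), "n_parents")
  expect_error(select_reproduce(pop, rep(1, 10)), "lengths differ")
})

test_that("run_scenario is deterministic, keeps population size, and selection helps", {
  cfg <- scenario_config("t", n_blocks = 1, generations = 40,
                         n_replicates = 2, master_seed = 11)
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_equal(r1$best_genomes[[1]]$w_ih, r2$best_genomes[[1]]$w_ih)
  # replicates use distinct input sets / populations
  expect_false(identical(r1$best_genomes[[1]]$w_ih, r1$best_genomes[[2]]$w_ih))

  expect_true(all(lengths(r1$final_populations) == 50))
  expect_true(all(r1$trajectory$best_fitness >= r1$trajectory$mean_fitness))
  expect_equal(nrow(r1$trajectory), 2 * 40)

  # zero generations: empty trajectory
  cfg0 <- scenario_config("t0", n_blocks = 1, generations = 0,
                          n_replicates = 1)
  r0 <- run_scenario(cfg0)
  expect_equal(nrow(r0$trajectory), 0)
  expect_length(r0$final_populations[[1]], 50)
})

test_that("a fixed PMN mask stays bit-identical under connective mode none", {
  cfg <- scenario_config("pmn_fixed", n_blocks = 1,
                         connective_regime = connective_regime("none"),
                         start_arch = "pmn", generations = 25,
                         n_replicates = 1, master_seed = 3)
  r <- run_scenario(cfg)
  pmn_mask <- make_architecture_mask(architecture_spec("pmn", 8, 4))
  for (g in r$final_populations[[1]]) expect_identical(g$m_ih, pmn_mask)
  expect_true(all(r$trajectory$active_count == 32L))
})

test_that("neutral drift of the active fraction follows the closed form", {
  # selection disabled: each of the 50 x 128 mask entries is an independent
  # two-state chain, so E[f(t)] = 0.5 + (f0 - 0.5) (1 - 2p)^t
  p <- 0.01
  cfg <- scenario_config("drift", n_blocks = 2,
                         weight_regime = weight_regime("every_weight", sd = 0),
                         connective_regime = connective_regime("symmetric", p),
                         generations = 201, n_replicates = 1,
                         selection = FALSE, master_seed = 17)
  r <- run_scenario(cfg)
  traj <- r$trajectory
  n_entries <- 50 * 16 * 8
  for (g in c(51, 201)) {
    t <- g - 1  # generation g is recorded after t mutation passes
    f_expected <- 0.5 + 0.5 * (1 - 2 * p)^t
    obs <- traj$mean_active_fraction[traj$generation == g]
    se <- sqrt(f_expected * (1 - f_expected) / n_entries)
    expect_lt(abs(obs - f_expected), 3 * se)
  }
})

test_that("temporally separated evolution alternates the two processes", {
  r <- run_temporal_separation(rounds = 3, inner_generations = 2,
                               flip_prob = 0, n_blocks = 1,
                               n_replicates = 1, master_seed = 5)
  # flip_prob 0 reduces to weight-only evolution: masks stay full
  expect_true(all(r$trajectory$active_fraction == 1))
  expect_equal(nrow(r$trajectory), 3)
  expect_true(all(r$trajectory$best_fitness >= r$trajectory$mean_fitness))

  r2 <- run_temporal_separation(rounds = 2, inner_generations = 2,
                                flip_prob = 1 / 400, n_blocks = 1,
                                n_replicates = 2, master_seed = 5)
  expect_equal(nrow(r2$trajectory), 4)
  expect_true(all(lengths(r2$final_populations) == 50))
})

test_that("presets encode the study scenarios", {
  expect_setequal(scenario_presets(),
                  c("starting_state", "small", "low_weight_rate",
                    "start_empty", "irreversible", "dull_task",
                    "dull_task_pmn", "very_large", "aggressive",
                    "temporal_separation", "starting_state_desk",
                    "small_desk"))
  ss <- scenario_preset("starting_state")
  expect_equal(ss$n_inputs, 96)
  expect_equal(ss$n_hidden, 48)
  expect_equal(ss$weight_regime$sd, 0.25)
  expect_equal(ss$weight_regime$prob, 1)
  expect_equal(ss$connective_regime$flip_prob, 0.001)
  expect_equal(ss$generations, 10000)
  expect_equal(ss$n_replicates, 20)
  expect_equal(ss$pop_size, 50)

  vl <- scenario_preset("very_large")
  expect_equal(c(vl$n_inputs, vl$n_hidden), c(144, 72))
  lw <- scenario_preset("low_weight_rate")
  expect_equal(lw$weight_regime$prob, 1 / 1000)
  expect_equal(lw$weight_regime$sd, 1)
  agg <- scenario_preset("aggressive")
  expect_equal(agg$connective_regime$flip_prob, 1 / 100)
  expect_equal(scenario_preset("start_empty")$start_arch, "empty")
  expect_equal(scenario_preset("irreversible")$connective_regime$mode,
               "irreversible_loss")
  expect_equal(scenario_preset("dull_task")$task_kind, "dull_intense")
  expect_equal(scenario_preset("dull_task_pmn")$start_arch, "pmn")
  expect_error(scenario_preset("unknown_thing"), "available presets")
})
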