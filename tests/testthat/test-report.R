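test_that("the modularity report scores evolved masks against their nulls", {
  pmn <- make_architecture_mask(architecture_spec("pmn", 16, 8))
  rep <- modularity_report(list(pmn, pmn), n_null = 10, n_groups = 2,
                           seed = 3, methods = "tabu")
  expect_s3_class(rep, "modularity_report")
  expect_equal(nrow(rep$scores), 2 * (1 + 10))
  expect_setequal(unique(rep$scores$network), c("evolved", "null"))
  s <- rep$summary
  expect_true(all(s$ci_lower <= s$ci_upper))
  # intact PMNs are more modular than their degree-preserving nulls
  ev <- s[s$network == "evolved", ]
  nu <- s[s$network == "null", ]
  expect_gt(ev$mean_q, nu$mean_q)
  expect_gt(ev$ci_lower, nu$ci_upper)
  expect_false(ci_overlap(rep)$overlap)

  expect_error(modularity_report(list(pmn), n_null = 1), "n_null")
})

test_that("a full mask equals its null exactly (the rewiring is forced)", {
  full <- matrix(TRUE, 8, 4)
  rep <- modularity_report(list(full), n_null = 3, n_groups = 2, seed = 1)
  q <- rep$scores$q
  for (m in unique(rep$scores$method)) {
    qm <- rep$scores$q[rep$scores$method == m]
    expect_true(all(qm == qm[1]))
  }
  expect_true(all(ci_overlap(rep)$overlap))
})

test_that("reports are deterministic in the seed and tidy correctly", {
  g <- init_genome(8, 4, seed = 2)
  set.seed(10)
  g$m_ih[sample.int(32, 16)] <- FALSE
  r1 <- modularity_report(list(g), n_null = 4, seed = 7)
  r2 <- modularity_report(list(g), n_null = 4, seed = 7)
  expect_identical(r1$scores, r2$scores)
  expect_identical(tidy(r1), r1$scores)
  expect_identical(glance(r1), r1$summary)
})

test_that("runs write complete output directories that reload", {
  cfg <- scenario_config("io_test", n_blocks = 1, generations = 10,
                         n_replicates = 2, master_seed = 13)
  run <- run_scenario(cfg)
  dir <- file.path(tempdir(), "modnet_run_io")
  write_run(run, dir)
  expect_true(file.exists(file.path(dir, "trajectory.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  traj <- readr::read_csv(file.path(dir, "trajectory.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(traj), nrow(run$trajectory))
  genomes <- read_run_genomes(dir)
  expect_length(genomes, 2)
  expect_equal(genomes[[1]]$w_ih, run$best_genomes[[1]]$w_ih)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$config$name, "io_test")
  expect_length(manifest$replicate_seeds, 2)
  unlink(dir, recursive = TRUE)
})

test_that("tidiers and plots cover the main result types", {
  cfg <- scenario_config("tidy_test", n_blocks = 1, generations = 8,
                         n_replicates = 1, master_seed = 4)
  run <- run_scenario(cfg)
  expect_identical(tidy(run), run$trajectory)
  gl <- glance(run)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$scenario, "tidy_test")
  expect_s3_class(autoplot(run), "ggplot")

  dcfg <- duplication_config(stage_generations = 12, branch_generation = 4,
                             module_sequence = c(1, 2), n_replicates = 1,
                             master_seed = 4)
  drun <- run_duplication_experiment(dcfg)
  expect_identical(tidy(drun), drun$trajectory)
  expect_equal(nrow(glance(drun)), 1)
  expect_s3_class(autoplot(drun), "ggplot")

  rep <- modularity_report(run$best_genomes, n_null = 3, seed = 2)
  expect_s3_class(autoplot(rep), "ggplot")

  p <- tabu_factions(two_triangle_graph(), 2, tabu_params(seed = 1))
  td <- tidy(p)
  expect_equal(nrow(td), 6)
  expect_named(td, c("node", "group"))
})

test_that("the command line dispatches, errors usefully, and is reproducible", {
  out1 <- file.path(tempdir(), "cli_run1")
  out2 <- file.path(tempdir(), "cli_run2")
  args <- c("simulate", "--preset", "small", "--generations", "12",
            "--replicates", "2", "--seed", "3")
  expect_equal(suppressMessages(run_cli(c(args, "--out", out1))), 0L)
  expect_equal(suppressMessages(run_cli(c(args, "--out", out2))), 0L)
  expect_identical(readLines(file.path(out1, "trajectory.csv")),
                   readLines(file.path(out2, "trajectory.csv")))

  mod_out <- file.path(tempdir(), "cli_mod")
  expect_equal(suppressMessages(
    run_cli(c("modularity", "--genomes", out1, "--n-null", "3",
              "--groups", "2", "--seed", "1", "--out", mod_out))), 0L)
  expect_true(file.exists(file.path(mod_out, "modularity_report.json")))
  expect_true(file.exists(file.path(mod_out, "modularity_scores.csv")))

  dup_out <- file.path(tempdir(), "cli_dup")
  expect_equal(suppressMessages(
    run_cli(c("duplicate", "--stages", "1,2", "--stage-generations", "10",
              "--branch", "4", "--replicates", "1", "--seed", "2",
              "--out", dup_out))), 0L)
  expect_true(file.exists(file.path(dup_out, "branch_summary.csv")))

  expect_equal(suppressMessages(run_cli(c("simulate", "--preset", "nope",
                                          "--out", out1))), 1L)
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(run_cli(character(0))), 1L)
  expect_output(expect_equal(run_cli("presets"), 0L), "starting_state")
  unlink(c(out1, out2, mod_out, dup_out), recursive = TRUE)
})
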