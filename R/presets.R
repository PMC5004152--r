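preset_table <- function(master_seed = 1L) {
  sd025_all <- weight_regime("every_weight", sd = 0.25)
  low_rate <- weight_regime("per_weight_prob", prob = 1 / 1000, sd = 1)
  sym <- connective_regime("symmetric", 0.001)
  list(
    # canonical large network: 96-48-1, every-weight mutation, symmetric flips
    starting_state = scenario_config(
      "starting_state", n_blocks = 12L, weight_regime = sd025_all,
      connective_regime = sym, generations = 10000L, n_replicates = 20L,
      master_seed = master_seed),
    # 16-8-1 network, otherwise as the starting state
    small = scenario_config(
      "small", n_blocks = 2L, weight_regime = sd025_all,
      connective_regime = sym, generations = 10000L, n_replicates = 20L,
      master_seed = master_seed),
    # large network, rare but larger weight mutations (p = 1/1000, sd 1)
    low_weight_rate = scenario_config(
      "low_weight_rate", n_blocks = 12L, weight_regime = low_rate,
      connective_regime = sym, generations = 10000L, n_replicates = 20L,
      master_seed = master_seed),
    # as low_weight_rate but growth from no input-to-hidden connections
    start_empty = scenario_config(
      "start_empty", n_blocks = 12L, weight_regime = low_rate,
      connective_regime = sym, start_arch = "empty", generations = 10000L,
      n_replicates = 20L, master_seed = master_seed),
    # connections can only be lost, never regained
    irreversible = scenario_config(
      "irreversible", n_blocks = 12L, weight_regime = low_rate,
      connective_regime = connective_regime("irreversible_loss", 0.001),
      generations = 10000L, n_replicates = 20L, master_seed = master_seed),
    # dull/intense discrimination task (140 dulled rows)
    dull_task = scenario_config(
      "dull_task", n_blocks = 12L, task_kind = "dull_intense",
      weight_regime = low_rate, connective_regime = sym,
      generations = 10000L, n_replicates = 20L, master_seed = master_seed),
    # dull/intense control on a fixed perfectly modular architecture
    dull_task_pmn = scenario_config(
      "dull_task_pmn", n_blocks = 12L, task_kind = "dull_intense",
      weight_regime = low_rate, connective_regime = connective_regime("none"),
      start_arch = "pmn", generations = 10000L, n_replicates = 20L,
      master_seed = master_seed),
    # 144-72-1 network
    very_large = scenario_config(
      "very_large", n_blocks = 18L, weight_regime = low_rate,
      connective_regime = sym, generations = 10000L, n_replicates = 20L,
      master_seed = master_seed),
    # every-weight mutation plus tenfold connective mutation rate
    aggressive = scenario_config(
      "aggressive", n_blocks = 12L, weight_regime = sd025_all,
      connective_regime = connective_regime("symmetric", 1 / 100),
      generations = 10000L, n_replicates = 20L, master_seed = master_seed),
    # alternating structural/weight evolution; run via run_temporal_separation()
    temporal_separation = scenario_config(
      "temporal_separation", n_blocks = 12L,
      weight_regime = weight_regime("per_weight_prob", prob = 1 / 400, sd = 1),
      connective_regime = connective_regime("symmetric", 1 / 400),
      generations = 400L, n_replicates = 8L, master_seed = master_seed),
    # desk-scale variants: same regimes, shorter runs and fewer replicates,
    # sized so the connection-mask drift has converged (time constant
    # 1/(2p) = 500 generations at p = 0.001)
    starting_state_desk = scenario_config(
      "starting_state_desk", n_blocks = 12L, weight_regime = sd025_all,
      connective_regime = sym, generations = 3000L, n_replicates = 3L,
      master_seed = master_seed),
    small_desk = scenario_config(
      "small_desk", n_blocks = 2L, weight_regime = sd025_all,
      connective_regime = sym, generations = 1500L, n_replicates = 3L,
      master_seed = master_seed)
  )
}

#' Named scenario presets
#'
#' `scenario_presets()` lists the available preset names;
#' `scenario_preset(name)` returns the corresponding [scenario_config()].
#' The nine study scenarios are `starting_state` (96-48-1, every-weight
#' Normal(0, 0.25) mutation, symmetric connective flips at 0.001), `small`
#' (16-8-1), `low_weight_rate` (per-weight probability 1/1000, sd 1),
#' `start_empty`, `irreversible`, `dull_task` (plus the `dull_task_pmn`
#' fixed-architecture control), `very_large` (144-72-1),
#' `temporal_separation` (run with [run_temporal_separation()]) and
#' `aggressive` (flip probability 1/100). The `*_desk` presets are
#' desk-scale versions with identical regimes but shorter runs.
#'
#' @param name Preset name.
#' @param master_seed Master seed stored in the returned config.
#' @param generations,n_replicates Optional overrides.
#' @return `scenario_preset()`: a `scenario_config`; `scenario_presets()`: a
#'   character vector of names.
#' @examples
#' scenario_presets()
#' scenario_preset("small", generations = 10, n_replicates = 1)
#' @export
scenario_preset <- function(name, master_seed = 1L, generations = NULL,
                            n_replicates = NULL) {
  tab <- preset_table(master_seed)
  if (!name %in% names(tab)) {
    stop("unknown preset '", name, "'; available presets: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  cfg <- tab[[name]]
  if (!is.null(generations)) cfg$generations <- as.integer(generations)
  if (!is.null(n_replicates)) cfg$n_replicates <- as.integer(n_replicates)
  cfg
}

#' @rdname scenario_preset
#' @export
scenario_presets <- function() {
  names(preset_table())
}
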