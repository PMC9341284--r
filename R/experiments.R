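#' Default experiment configuration
#'
#' All tunable constants of the two experimental phases in one nested list:
#' grid geometry, population sizes and partition, LIF/STDP constants, the
#' training schedule, and the reinforcement-learning hyperparameters.
#' Round-trips losslessly through YAML via [write_config()]/[read_config()].
#'
#' @param seed RNG seed used by the drivers.
#' @return A nested list of class `experiment_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    grid = list(width = 11, height = 7, cell_length = 25, wall_col = 6,
                danger_cell = c(2, 4),
                switch_cell_phase1 = c(4, 6),
                switch_cell_phase2 = c(10, 6),
                passage_cell = c(6, 4),
                start_phase1 = c(3, 3),
                start_a = c(7, 2), start_b = c(4, 4)),
    network = list(n_emotion = 40, n_motor = 50, n_perception = 40,
                   sma_sizes = c(5, 5), m1_sizes = c(4, 2, 4),
                   mirror_sizes = c(6, 6, 6, 6, 6),
                   inh_gain = 2.5, act_window = 25, init_inhibitory = 0.01),
    lif = list(u_rest = 0, u_reset = 0, u_th = 60, tau_m = 30, R = 1, dt = 1),
    stdp = list(A_plus = 0.25, A_minus = 0.01, tau_plus = 10, tau_minus = 10,
                window = 50, w_min = 0, w_max = 1),
    schedule = list(motor_to_action_latency = 100,
                    action_to_perception_latency = 100,
                    motor_firing_duration = 350, reafference_duration = 100,
                    epochs = 100, epoch_gap = 300),
    exploration = list(max_steps = 400),
    rl = list(alpha = 0.1, gamma = 0.9, epsilon = 0.1, epsilon_decay = 0.99,
              episodes = 300, max_steps = 120,
              relief_reward = 10, pain_penalty = -1, step_cost = -0.01)),
    class = "experiment_config")
}

#' Read / write an experiment configuration
#'
#' @param path YAML file path.
#' @param config An [default_config()]-shaped list.
#' @return `read_config()` returns an `experiment_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  needed <- c("seed", "grid", "network", "lif", "stdp", "schedule",
              "exploration", "rl")
  missing <- setdiff(needed, names(cfg))
  if (length(missing))
    stop("configuration is missing keys: ", paste(missing, collapse = ", "))
  invisible(cfg)
}

config_objects <- function(cfg) {
  list(
    lif = do.call(lif_params, cfg$lif),
    stdp = do.call(stdp_params, cfg$stdp),
    spec = module_spec(cfg$network$n_emotion, cfg$network$n_motor,
                       cfg$network$n_perception, cfg$network$sma_sizes,
                       cfg$network$m1_sizes, cfg$network$mirror_sizes),
    schedule = do.call(training_schedule, cfg$schedule))
}

#' Phase 1: solo exploration, pain sensing, and empathy training
#'
#' The explorer random-walks the danger zone, predicting each move with the
#' healthy movement rule and scoring the prediction error as free energy:
#' colliding with the dangerous object inverts its motor commands and drives
#' the free energy (hence pain) positive until it touches the danger-side
#' switch and escapes to the safety zone. The empathy network is then
#' trained by execution + re-afference epochs on both emotion channels, with
#' a per-epoch empathy probe.
#'
#' @param config An [default_config()] list.
#' @param out_dir Optional directory for `fe_trace.csv`, `spikes.csv`,
#'   `weights.csv` and `weights_final.csv`.
#' @return A list of class `run_report`: `fe_trace`, `net` (trained),
#'   `trajectory`, `empathy_epoch`, `epoch_raster`, and `files`.
#' @export
run_phase1 <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  set.seed(config$seed)
  obj <- config_objects(config)
  g <- config$grid
  world <- grid_world(g$width, g$height, g$cell_length, g$wall_col,
                      danger_cell = g$danger_cell,
                      switch_cell = g$switch_cell_phase1,
                      passage_cells = g$passage_cell)
  agent <- agent_state("A", g$start_phase1, world)
  rows <- vector("list", config$exploration$max_steps)
  for (step in seq_len(config$exploration$max_steps)) {
    # once the passage is open a damaged explorer heads straight for the
    # safety zone to recover; otherwise it keeps exploring at random
    cmd <- if (world$passage_open && agent$damaged)
      escape_command(world, agent) else random_walk_policy()
    before <- agent
    res <- step_agent(world, agent, cmd)
    world <- res$world
    sensed <- sense_self(world, before, cmd, res$agent)
    agent <- sensed$agent
    rows[[step]] <- data.frame(step = step,
                               fe_raw = sensed$report$fe_raw,
                               fe_clipped = sensed$report$fe_clipped,
                               pain = sensed$report$pain,
                               event = paste(res$events, collapse = "+"))
    if ("recovery" %in% res$events) { rows <- rows[seq_len(step)]; break }
  }
  fe_trace <- do.call(rbind, rows)

  net <- build_network(obj$spec, obj$lif, obj$stdp,
                       inh_gain = config$network$inh_gain,
                       act_window = config$network$act_window,
                       init_inhibitory = config$network$init_inhibitory)
  epoch_raster <- run_execution_epoch(net, "pain", obj$schedule,
                                      learn = FALSE)$raster
  trained <- train_network(net, c("pain", "normal"), obj$schedule, probe = TRUE)

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      write_fe_trace(fe_trace, file.path(out_dir, "fe_trace.csv")),
      write_raster(epoch_raster, file.path(out_dir, "spikes.csv")),
      write_weights(trained$trajectory, file.path(out_dir, "weights.csv")),
      write_weights(trained$net, file.path(out_dir, "weights_final.csv")))
  }
  structure(list(fe_trace = fe_trace, net = trained$net,
                 trajectory = trained$trajectory,
                 empathy = trained$empathy,
                 empathy_epoch = trained$empathy_epoch,
                 epoch_raster = epoch_raster, files = files),
            class = "run_report")
}

#' Phase 2: the two-agent altruistic rescue task
#'
#' Builds the rescue scenario around the phase-1 network, trains the
#' intrinsic-reward Q-learning policy, and records the observation-phase
#' raster (the explorer's red percept presented to the observer's network).
#'
#' @param config An [default_config()] list.
#' @param net A trained network from [run_phase1()].
#' @param out_dir Optional directory for `rescue_log.csv`, `qtable.csv` and
#'   `spikes_observation.csv`.
#' @return A list of class `run_report`: `q`, `log`, `greedy_steps`,
#'   `shortest_path`, `observation_raster`, `scenario`, `files`.
#' @export
run_phase2 <- function(config = default_config(), net, out_dir = NULL) {
  validate_config(config)
  if (missing(net) || is.null(net)) stop("run_phase2 needs a phase-1 network")
  set.seed(config$seed + 1L)
  g <- config$grid
  world <- grid_world(g$width, g$height, g$cell_length, g$wall_col,
                      danger_cell = g$danger_cell,
                      switch_cell = g$switch_cell_phase2,
                      passage_cells = g$passage_cell)
  rl <- config$rl
  scenario <- rescue_scenario(net, world, g$start_a, g$start_b,
                              max_steps = rl$max_steps,
                              rewards = reward_model(rl$relief_reward,
                                                     rl$pain_penalty,
                                                     rl$step_cost))
  q0 <- q_table(world, rl$alpha, rl$gamma, rl$epsilon)
  trained <- train_rescue(scenario, episodes = rl$episodes, q = q0,
                          epsilon_decay = rl$epsilon_decay)
  greedy <- greedy_steps_to_switch(scenario, trained$q)
  dist <- bfs_distances(world, g$start_a)
  shortest <- dist[world$switch_cell[1], world$switch_cell[2]]
  obs_raster <- observe_other(net, "perceive-red")$raster
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    qdf <- data.frame(state = rownames(trained$q$values), trained$q$values)
    files <- c(
      local({ p <- file.path(out_dir, "rescue_log.csv")
        utils::write.csv(trained$log, p, row.names = FALSE, quote = FALSE); p }),
      local({ p <- file.path(out_dir, "qtable.csv")
        utils::write.csv(qdf, p, row.names = FALSE, quote = FALSE); p }),
      write_raster(obs_raster, file.path(out_dir, "spikes_observation.csv")))
  }
  structure(list(q = trained$q, log = trained$log, greedy_steps = greedy,
                 shortest_path = shortest, observation_raster = obs_raster,
                 scenario = scenario, files = files),
            class = "run_report")
}

#' Motor-neuron census of a trained network
#'
#' @param net A trained network.
#' @param out_dir Optional directory for `census.csv`.
#' @return The [classify_neurons()] result, with `files`.
#' @export
run_census <- function(net, out_dir = NULL) {
  res <- classify_neurons(net)
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(out_dir, "census.csv")
    utils::write.csv(res$census, p, row.names = FALSE)
    files <- p
  }
  res$files <- files
  res
}

#' Plot helpers for the emitted CSV records
#'
#' Base-graphics figures regenerated from the CSV records (never from
#' in-memory state): the free-energy trace, a spike raster, and the plastic
#' weight trajectories.
#'
#' @param path CSV file emitted by the phase drivers.
#' @param ... Passed to the underlying plot call.
#' @return Invisibly, the data that was plotted.
#' @export
plot_fe_trace <- function(path, ...) {
  df <- utils::read.csv(path)
  plot(df$step, df$fe_clipped, type = "s", xlab = "step",
       ylab = "free energy (clipped)", ...)
  invisible(df)
}

#' @rdname plot_fe_trace
#' @export
plot_spike_raster <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mods <- unique(df$module)
  offset <- stats::setNames(cumsum(c(0, utils::head(tapply(df$neuron_index, df$module, max)[mods], -1))), mods)
  y <- df$neuron_index + offset[df$module]
  plot(df$time_ms, y, pch = ".", cex = 2, xlab = "time (ms)",
       ylab = "neuron (stacked by module)", ...)
  invisible(df)
}

#' @rdname plot_fe_trace
#' @export
plot_weight_trajectory <- function(path, ...) {
  df <- utils::read.csv(path)
  graphics::matplot(df$epoch, df[, c("sma_inhibitory", "m1", "mirror_excitatory")],
          type = "l", lty = 1, xlab = "epoch", ylab = "mean weight", ...)
  graphics::legend("right", legend = c("perception->SMA (inhibitory)",
                                       "perception->M1", "perception->mirror"),
                   lty = 1, col = 1:3, bty = "n")
  invisible(df)
}
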