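#' Tabular Q-table over (cell, passage flag) states
#'
#' State space: every grid cell crossed with the passage-open flag; actions
#' are the four cardinal commands. The observing agent's policy never sees
#' the other agent's position — only its own cell, the passage flag, and
#' (through the reward) its own empathized emotion.
#'
#' @param world A [grid_world()].
#' @param alpha Learning rate (default 0.1).
#' @param gamma Discount factor (default 0.9).
#' @param epsilon Initial exploration rate (default 0.1).
#' @return An object of class `q_table`: a zero matrix of states x actions
#'   with the hyperparameters attached.
#' @export
q_table <- function(world, alpha = 0.1, gamma = 0.9, epsilon = 0.1) {
  cells <- expand.grid(col = seq_len(world$width), row = seq_len(world$height),
                       open = c(FALSE, TRUE))
  keys <- sprintf("%d:%d:%d", cells$col, cells$row, as.integer(cells$open))
  values <- matrix(0, nrow = length(keys), ncol = 4,
                   dimnames = list(keys, c("up", "down", "left", "right")))
  structure(list(values = values, alpha = alpha, gamma = gamma,
                 epsilon = epsilon),
            class = "q_table")
}

state_key <- function(cell, open) {
  sprintf("%d:%d:%d", cell[1], cell[2], as.integer(open))
}

#' One tabular Q-learning update
#'
#' `Q(s,a) <- Q(s,a) + alpha * (r + gamma * max_a' Q(s',a') - Q(s,a))`.
#'
#' @param q A [q_table()].
#' @param s,s_next State keys (see the `q_table` row names).
#' @param a Action name.
#' @param r Scalar reward.
#' @return The updated `q_table`.
#' @export
q_update <- function(q, s, a, r, s_next) {
  if (!s %in% rownames(q$values) || !s_next %in% rownames(q$values))
    stop("unknown state key")
  target <- r + q$gamma * max(q$values[s_next, ])
  q$values[s, a] <- q$values[s, a] + q$alpha * (target - q$values[s, a])
  q
}

#' Intrinsic reward from an empathized emotion transition
#'
#' Runs the observer's network on the percept of the other agent's overt
#' action and converts the resulting empathized-emotion transition into a
#' scalar: a positive relief reward on the step empathized pain ends, a
#' per-step penalty while it persists, and a small step cost otherwise. The
#' reward is a pure function of the observer's own internal emotion
#' transition — never of privileged access to the other agent's state.
#'
#' @param net The observer's trained [build_network()] object.
#' @param percept The percept of the other agent's color.
#' @param previous_pain Logical: was empathized pain active on the previous
#'   step?
#' @param rewards A list with `relief_reward` (> 0), `pain_penalty` (< 0 per
#'   pain step) and `step_cost` (small, <= 0).
#' @return A list with `reward` and `pain` (the new empathized-pain flag).
#' @export
empathic_reward <- function(net, percept, previous_pain = FALSE,
                            rewards = reward_model()) {
  if (net$epochs_trained == 0L)
    stop("empathic_reward needs a trained network")
  obs <- observe_other(net, percept)
  pain <- isTRUE(obs$emotion_blocks[["pain"]])
  list(reward = transition_reward(previous_pain, pain, rewards), pain = pain)
}

#' Intrinsic reward magnitudes
#'
#' @param relief_reward Reward on the pain -> no-pain transition (default 10).
#' @param pain_penalty Reward per step of persisting empathized pain
#'   (default -1).
#' @param step_cost Reward on ordinary steps (default -0.01).
#' @return A validated list of the three magnitudes.
#' @export
reward_model <- function(relief_reward = 10, pain_penalty = -1,
                         step_cost = -0.01) {
  stopifnot(relief_reward > 0, step_cost <= 0, pain_penalty < 0)
  list(relief_reward = relief_reward, pain_penalty = pain_penalty,
       step_cost = step_cost)
}

transition_reward <- function(previous_pain, pain, rewards) {
  if (previous_pain && !pain) rewards$relief_reward
  else if (pain) rewards$pain_penalty
  else rewards$step_cost
}

#' Two-agent rescue scenario
#'
#' The observer (agentA, trained network, safety zone) learns to rescue the
#' explorer (agentB, random walk, danger zone). The switch sits on the
#' safety side, so agentB cannot rescue itself. The observer's emotion
#' response to each percept is computed once from its network and cached;
#' the per-step reward then follows from its empathized-emotion transitions.
#'
#' @param net The observer's trained network (or an untrained one for
#'   ablation controls).
#' @param world A [grid_world()] with a safety-side switch.
#' @param start_a,start_b Starting cells for observer and explorer.
#' @param max_steps Step cap per episode (default 120).
#' @param rewards A [reward_model()].
#' @param danger_active Set `FALSE` to disable the dangerous object (control
#'   episodes in which the explorer never feels pain).
#' @return An object of class `rescue_scenario`.
#' @export
rescue_scenario <- function(net, world = grid_world(switch_cell = c(10, 6)),
                            start_a = c(7, 2), start_b = c(4, 4),
                            max_steps = 120, rewards = reward_model(),
                            danger_active = TRUE) {
  if (cell_zone(world, world$switch_cell) != "safety")
    stop("the rescue switch must sit in the safety zone")
  if (cell_zone(world, start_a) != "safety") stop("agentA must start in safety")
  if (cell_zone(world, start_b) != "danger") stop("agentB must start in danger")
  pain_for <- c(
    "perceive-red" = isTRUE(observe_other(net, "perceive-red")$emotion_blocks[["pain"]]),
    "perceive-green" = isTRUE(observe_other(net, "perceive-green")$emotion_blocks[["pain"]]))
  structure(list(net = net, world = world, start_a = as.integer(start_a),
                 start_b = as.integer(start_b), max_steps = max_steps,
                 rewards = rewards, danger_active = danger_active,
                 pain_for = pain_for),
            class = "rescue_scenario")
}

#' Run one rescue episode
#'
#' Per synchronous turn: the observer — whose altruistic action is motivated
#' solely by its empathized negative emotion, so it rests until pain is
#' shared — acts (epsilon-greedy on the Q-table, or greedy, or uniformly
#' random), possibly opening the passage by touching the switch; the
#' explorer random-walks its own zone (switching to the shortest escape
#' route to the safety zone once it is damaged and the passage is open); the
#' observer perceives the explorer's color and receives its intrinsic
#' reward. The episode succeeds on the step the observer's empathized pain
#' is relieved, i.e. after the explorer has recovered in the safety zone.
#'
#' @param scenario A [rescue_scenario()].
#' @param q A [q_table()].
#' @param greedy Use the greedy policy (no exploration)?
#' @param learn Update the Q-table in place?
#' @param random_policy Ignore the Q-table and act uniformly at random
#'   (chance baseline)?
#' @param epsilon Exploration rate override (default the table's).
#' @return A list: `q`, `steps`, `success`, `total_reward`, and `events`
#'   (data frame `step`, `event` over `b_pain`, `switch`, `b_recovery`,
#'   `a_relief`).
#' @export
run_rescue_episode <- function(scenario, q, greedy = FALSE, learn = TRUE,
                               random_policy = FALSE, epsilon = q$epsilon) {
  world <- scenario$world
  world$passage_open <- FALSE
  a <- agent_state("A", scenario$start_a, world)
  b <- agent_state("B", scenario$start_b, world)
  prev_pain <- FALSE
  total_reward <- 0
  ev_step <- integer(); ev_what <- character()
  actions <- colnames(q$values)
  success <- FALSE
  steps_used <- scenario$max_steps
  for (step in seq_len(scenario$max_steps)) {
    # Altruistic action is driven by the empathized negative emotion: while
    # the observer feels no empathized pain it has no motivation to act and
    # rests; once pain is shared, it acts to eliminate it.
    motivated <- prev_pain
    if (motivated) {
      s <- state_key(a$cell, world$passage_open)
      act <- if (random_policy || (!greedy && stats::runif(1) < epsilon)) {
        sample(actions, 1L)
      } else {
        qs <- q$values[s, ]
        top <- which(qs == max(qs))
        actions[if (length(top) > 1L) sample(top, 1L) else top]
      }
      res_a <- step_agent(world, a, act)
      world <- res_a$world; a <- res_a$agent
      if ("switch" %in% res_a$events) { ev_step <- c(ev_step, step); ev_what <- c(ev_what, "switch") }
    }

    # A damaged explorer flees to the safety zone to recover once the
    # passage is open; a healthy one keeps exploring its own zone (the
    # passage is of no use to it).
    fleeing <- world$passage_open && b$damaged &&
      cell_zone(world, b$cell) != "safety"
    cmd_b <- if (fleeing) escape_command(world, b) else random_walk_policy()
    world_b <- world
    if (!fleeing && cell_zone(world, b$cell) == "danger")
      world_b$passage_open <- FALSE
    b_before <- b
    res_b <- step_agent(world_b, b, cmd_b)
    res_b$world <- world
    if (!scenario$danger_active) res_b$agent$damaged <- FALSE
    world <- res_b$world
    sensed <- sense_self(world_b, b_before, cmd_b, res_b$agent)
    b <- sensed$agent
    if ("collision" %in% res_b$events && scenario$danger_active) {
      ev_step <- c(ev_step, step); ev_what <- c(ev_what, "b_pain")
    }
    if ("recovery" %in% res_b$events) {
      ev_step <- c(ev_step, step); ev_what <- c(ev_what, "b_recovery")
    }

    percept <- perceive_other(a, b)
    pain_now <- unname(scenario$pain_for[[percept]])
    if (motivated) {
      r <- transition_reward(prev_pain, pain_now, scenario$rewards)
      total_reward <- total_reward + r
      s_next <- state_key(a$cell, world$passage_open)
      if (learn) q <- q_update(q, s, act, r, s_next)
    }
    if (prev_pain && !pain_now) {
      ev_step <- c(ev_step, step); ev_what <- c(ev_what, "a_relief")
      success <- TRUE
      steps_used <- step
      prev_pain <- pain_now
      break
    }
    prev_pain <- pain_now
  }
  list(q = q, steps = steps_used, success = success,
       total_reward = total_reward,
       events = data.frame(step = ev_step, event = ev_what,
                           stringsAsFactors = FALSE))
}

#' Train the rescue policy by intrinsic-reward Q-learning
#'
#' Runs epsilon-greedy episodes with a geometric exploration decay and logs
#' per-episode outcomes.
#'
#' @param scenario A [rescue_scenario()].
#' @param episodes Number of training episodes (default 300).
#' @param q Optional starting [q_table()].
#' @param epsilon_decay Multiplicative decay of the exploration rate per
#'   episode (default 0.99, floored at 0.01).
#' @param random_policy Train-time chance baseline: act uniformly at random
#'   throughout (the Q-table still updates, measuring what chance achieves).
#' @return A list: `q` (trained table) and `log` (data frame `episode`,
#'   `steps`, `success`, `total_reward`, `epsilon`).
#' @export
train_rescue <- function(scenario, episodes = 300, q = NULL,
                         epsilon_decay = 0.99, random_policy = FALSE) {
  if (is.null(q)) q <- q_table(scenario$world)
  eps <- q$epsilon
  log <- vector("list", episodes)
  for (ep in seq_len(episodes)) {
    res <- run_rescue_episode(scenario, q, greedy = FALSE, learn = TRUE,
                              random_policy = random_policy, epsilon = eps)
    q <- res$q
    log[[ep]] <- data.frame(episode = ep, steps = res$steps,
                            success = res$success,
                            total_reward = res$total_reward, epsilon = eps)
    eps <- max(0.01, eps * epsilon_decay)
  }
  list(q = q, log = do.call(rbind, log))
}

#' Greedy path length from the observer's start to the switch
#'
#' Rolls out the greedy policy on the observer's own state space (passage
#' closed) and counts the steps until the switch is touched; `NA` if the cap
#' is reached first.
#'
#' @param scenario A [rescue_scenario()].
#' @param q A trained [q_table()].
#' @param cap Step cap (default 100).
#' @return Integer step count or `NA`.
#' @export
greedy_steps_to_switch <- function(scenario, q, cap = 100) {
  world <- scenario$world
  world$passage_open <- FALSE
  a <- agent_state("A", scenario$start_a, world)
  actions <- colnames(q$values)
  for (step in seq_len(cap)) {
    s <- state_key(a$cell, world$passage_open)
    act <- actions[which.max(q$values[s, ])]
    res <- step_agent(world, a, act)
    world <- res$world; a <- res$agent
    if ("switch" %in% res$events) return(step)
  }
  NA_integer_
}
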