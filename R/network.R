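#' Population layout of the three-module empathy network
#'
#' Defines the population sizes and index blocks. Emotions and percepts are
#' population-coded: the pain state occupies the first half of the emotion
#' module, the normal state the second half; the percept of the red overt
#' action occupies the first half of the perception module, green the
#' second. The motor module is partitioned into two SMA groups (action
#' initiation, one per overt action), an M1 group (muscle command, driven
#' exclusively by SMA), and five mirror-candidate groups distinguished by
#' which emotions drive them and which percept blocks may grow plastic
#' synapses onto them.
#'
#' @param n_emotion,n_motor,n_perception Population sizes (defaults 40, 50, 40).
#' @param sma_sizes Sizes of the two SMA groups (default 5 each).
#' @param m1_sizes Sizes of the three M1 subgroups: wired from SMA group 1
#'   only, from both, and from SMA group 2 only (default 4, 2, 4).
#' @param mirror_sizes Sizes of the five mirror-candidate groups: driven by
#'   emotion 1 only, by emotion 2 only, and by both emotions with plastic
#'   input restricted to percept block 1, percept block 2, or unrestricted
#'   (default 6 each).
#' @return An object of class `module_spec` carrying the index blocks.
#' @export
module_spec <- function(n_emotion = 40, n_motor = 50, n_perception = 40,
                        sma_sizes = c(5, 5), m1_sizes = c(4, 2, 4),
                        mirror_sizes = c(6, 6, 6, 6, 6)) {
  stopifnot(n_emotion >= 2, n_perception >= 2,
            length(sma_sizes) == 2, length(m1_sizes) == 3,
            length(mirror_sizes) == 5,
            all(sma_sizes > 0), all(mirror_sizes > 0), all(m1_sizes >= 0))
  if (sum(sma_sizes, m1_sizes, mirror_sizes) != n_motor)
    stop("motor partition sizes must sum to n_motor")
  cuts <- cumsum(c(sma_sizes, m1_sizes, mirror_sizes))
  blk <- function(k) if (k == 1) seq_len(cuts[1]) else (cuts[k - 1] + 1):cuts[k]
  half_e <- n_emotion %/% 2
  half_p <- n_perception %/% 2
  structure(list(
    n_emotion = n_emotion, n_motor = n_motor, n_perception = n_perception,
    emotion_coding = list(pain = 1:half_e, normal = (half_e + 1):n_emotion),
    perception_coding = list(`perceive-red` = 1:half_p,
                             `perceive-green` = (half_p + 1):n_perception),
    overt_actions = c(pain = "red", normal = "green"),
    motor_partition = list(
      sma1 = blk(1), sma2 = blk(2),
      m1_from_sma1 = blk(3), m1_from_both = blk(4), m1_from_sma2 = blk(5),
      mirror1 = blk(6), mirror2 = blk(7),
      shared_p1 = blk(8), shared_p2 = blk(9), shared_pall = blk(10))),
    class = "module_spec")
}

# Convenience index sets over the motor partition.
motor_indices <- function(spec) {
  mp <- spec$motor_partition
  list(sma = c(mp$sma1, mp$sma2),
       m1 = c(mp$m1_from_sma1, mp$m1_from_both, mp$m1_from_sma2),
       mirror = c(mp$mirror1, mp$mirror2,
                  mp$shared_p1, mp$shared_p2, mp$shared_pall))
}

# Non-M1 motor neurons hereditarily wired to each emotion.
emotion_wired_motor <- function(spec) {
  mp <- spec$motor_partition
  shared <- c(mp$shared_p1, mp$shared_p2, mp$shared_pall)
  list(pain = c(mp$sma1, mp$mirror1, shared),
       normal = c(mp$sma2, mp$mirror2, shared))
}

#' Training schedule for execution + re-afference epochs
#'
#' Executing an overt action takes 100 ms from motor firing to the action,
#' and a further 100 ms from the action to the firing of the perception
#' neurons that register it, so re-afferent perception onset lags motor
#' onset by exactly 200 ms. Because execution is continuous, the motor
#' population keeps firing well past that delay, giving the temporal overlap
#' that drives STDP.
#'
#' @param motor_to_action_latency,action_to_perception_latency Latencies in
#'   ms (defaults 100 each); their sum is the re-afference delay.
#' @param motor_firing_duration How long (ms) the emotion drive — and hence
#'   motor firing — persists within an epoch; must exceed the total delay.
#' @param reafference_duration How long (ms) the re-afferent percept drive
#'   persists once it starts (default 100).
#' @param epochs Number of training epochs per emotion (default 100).
#' @param epoch_gap Silent gap between epochs (ms); the default 300 exceeds
#'   the STDP window so no spike pair straddles epochs.
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(motor_to_action_latency = 100,
                              action_to_perception_latency = 100,
                              motor_firing_duration = 350,
                              reafference_duration = 100,
                              epochs = 100, epoch_gap = 300) {
  total <- motor_to_action_latency + action_to_perception_latency
  if (!(motor_firing_duration > total))
    stop("motor_firing_duration must exceed the total re-afference delay")
  stopifnot(epochs >= 0, epoch_gap >= 0, reafference_duration > 0)
  structure(list(motor_to_action_latency = motor_to_action_latency,
                 action_to_perception_latency = action_to_perception_latency,
                 total_delay = total,
                 motor_firing_duration = motor_firing_duration,
                 reafference_duration = reafference_duration,
                 epochs = epochs, epoch_gap = epoch_gap),
            class = "training_schedule")
}

#' Build the three-population empathy network
#'
#' Wires the fixed ("hereditary") synapses and initializes the plastic
#' perception-to-motor matrix:
#' * emotion -> motor: excitatory, from each emotion block to every non-M1
#'   motor neuron wired to that emotion; transmitted only while an external
#'   emotional trigger is present (empathized emotion does not re-enter the
#'   motor module);
#' * SMA -> M1: excitatory and strong — an active SMA group activates its
#'   M1 neurons immediately; M1 receives no other input;
#' * motor -> emotion: the reverse read-out used to infer the emotion behind
#'   observed motor activity, wired from the action-specific groups (SMA and
#'   the emotion-specific mirror group) of each action;
#' * perception -> motor (plastic): near-zero initial weights, inhibitory
#'   onto SMA, excitatory onto mirror candidates, structurally absent onto
#'   M1; trained by STDP.
#'
#' Fixed synaptic gains are sized so that a fully active presynaptic block
#' delivers a drive of `2 * u_th`, giving the standard first-spike latency
#' of `tau_m * ln 2` (about 21 ms at the default constants).
#'
#' @param spec A [module_spec()].
#' @param lif A [lif_params()].
#' @param stdp An [stdp_params()].
#' @param inh_gain Current per unit inhibitory weight per active perception
#'   neuron onto SMA. The default 2.5 lets inhibition bias but never veto
#'   the hereditary execution drive (see the package vignette).
#' @param act_window A presynaptic neuron is treated as active for this many
#'   ms after a spike (default 25, just above one inter-spike interval).
#' @param init_inhibitory Initial magnitude of the inhibitory
#'   perception-to-SMA weights (default 0.01), giving STDP a direction to
#'   strengthen.
#' @return An object of class `empathy_network`.
#' @export
build_network <- function(spec = module_spec(), lif = lif_params(),
                          stdp = stdp_params(), inh_gain = 2.5,
                          act_window = 25, init_inhibitory = 0.01) {
  mp <- spec$motor_partition
  blocks <- unname(mp)
  all_idx <- sort(unlist(blocks))
  if (any(duplicated(unlist(blocks))) ||
      !identical(all_idx, seq_len(spec$n_motor)))
    stop("motor partition blocks must be disjoint and cover the population")
  mi <- motor_indices(spec)
  drive <- 2 * lif$u_th
  wired <- emotion_wired_motor(spec)

  W_em <- matrix(0, spec$n_emotion, spec$n_motor)
  W_em[spec$emotion_coding$pain, wired$pain] <- 1
  W_em[spec$emotion_coding$normal, wired$normal] <- 1

  W_mm <- matrix(0, spec$n_motor, spec$n_motor)
  W_mm[mp$sma1, c(mp$m1_from_sma1, mp$m1_from_both)] <- 1
  W_mm[mp$sma2, c(mp$m1_from_sma2, mp$m1_from_both)] <- 1

  W_me <- matrix(0, spec$n_motor, spec$n_emotion)
  W_me[c(mp$sma1, mp$mirror1), spec$emotion_coding$pain] <- 1
  W_me[c(mp$sma2, mp$mirror2), spec$emotion_coding$normal] <- 1

  mask <- matrix(1, spec$n_perception, spec$n_motor)
  mask[, mi$m1] <- 0
  mask[spec$perception_coding$`perceive-red`, mp$shared_p2] <- 0
  mask[spec$perception_coding$`perceive-green`, mp$shared_p1] <- 0
  w0 <- matrix(0, spec$n_perception, spec$n_motor)
  w0[, mi$sma] <- init_inhibitory
  plastic <- synapse_matrix(w0, polarity = "excitatory", plastic = TRUE,
                            mask = mask, params = stdp)
  plastic_sign <- rep(1, spec$n_motor)
  plastic_sign[mi$sma] <- -1
  plastic_sign[mi$m1] <- 0

  structure(list(
    spec = spec, lif = lif, stdp = stdp,
    W_emotion_motor = W_em, W_sma_m1 = W_mm, W_motor_emotion = W_me,
    W_perception_motor = plastic, plastic_sign = plastic_sign,
    gains = list(
      emotion_motor = drive / length(spec$emotion_coding$pain),
      sma_m1 = drive / length(mp$sma1),
      motor_emotion = drive / length(mp$mirror1),
      perception_exc = drive / length(spec$perception_coding$`perceive-red`),
      perception_inh = inh_gain),
    drive = drive, act_window = act_window,
    epochs_trained = 0L),
    class = "empathy_network")
}

# Core clock-driven simulation of the three coupled populations.
#
# emotion_idx / percept_idx: neuron blocks receiving external drive.
# emotion_window / percept_window: [on, off] step interval of that drive
# (local steps). percept_window = "reafference" schedules the percept drive
# so that perception onset lags the first motor spike by exactly
# `schedule$total_delay`, compensating for the LIF first-spike latency.
# trigger_gate: whether an external emotional trigger is present, enabling
# the forward emotion->motor projection.
simulate_network <- function(net, duration,
                             emotion_idx = NULL, emotion_window = NULL,
                             percept_idx = NULL, percept_window = NULL,
                             trigger_gate = TRUE, schedule = NULL, t0 = 0) {
  spec <- net$spec
  lif <- net$lif
  g <- net$gains
  Wp <- net$W_perception_motor$weights
  pgain <- ifelse(net$plastic_sign > 0, g$perception_exc,
                  ifelse(net$plastic_sign < 0, -g$perception_inh, 0))
  reaff <- identical(percept_window, "reafference")
  if (reaff && is.null(schedule)) stop("re-afference scheduling needs a schedule")
  lat <- lif_latency_steps(lif, net$drive)
  pop_e <- neuron_population(spec$n_emotion, lif); pop_e$t <- t0
  pop_m <- neuron_population(spec$n_motor, lif); pop_m$t <- t0
  pop_p <- neuron_population(spec$n_perception, lif); pop_p$t <- t0
  ev_mod <- character(); ev_idx <- integer(); ev_t <- numeric()
  motor_onset <- NA_real_
  p_on <- if (reaff) Inf else if (is.null(percept_window)) Inf else percept_window[1]
  p_off <- if (reaff) Inf else if (is.null(percept_window)) -Inf else percept_window[2]
  steps <- ceiling(duration / lif$dt)
  for (step in seq_len(steps)) {
    now <- t0 + step * lif$dt
    act_e <- active_mask(pop_e$last_spike_times, now, net$act_window, lif$dt)
    act_m <- active_mask(pop_m$last_spike_times, now, net$act_window, lif$dt)
    act_p <- active_mask(pop_p$last_spike_times, now, net$act_window, lif$dt)

    I_e <- g$motor_emotion * as.numeric(act_m %*% net$W_motor_emotion)
    if (!is.null(emotion_idx) && step >= emotion_window[1] &&
        step <= emotion_window[2])
      I_e[emotion_idx] <- I_e[emotion_idx] + net$drive

    I_m <- g$sma_m1 * as.numeric(act_m %*% net$W_sma_m1) +
      as.numeric(act_p %*% Wp) * pgain
    if (trigger_gate)
      I_m <- I_m + g$emotion_motor * as.numeric(act_e %*% net$W_emotion_motor)

    I_p <- numeric(spec$n_perception)
    if (!is.null(percept_idx) && step >= p_on && step <= p_off)
      I_p[percept_idx] <- net$drive

    se <- lif_step(pop_e, I_e, lif); pop_e <- se$pop
    sm <- lif_step(pop_m, I_m, lif); pop_m <- sm$pop
    sp <- lif_step(pop_p, I_p, lif); pop_p <- sp$pop

    if (length(se$fired)) { ev_mod <- c(ev_mod, rep("emotion", length(se$fired)))
      ev_idx <- c(ev_idx, se$fired); ev_t <- c(ev_t, rep(now, length(se$fired))) }
    if (length(sm$fired)) { ev_mod <- c(ev_mod, rep("motor", length(sm$fired)))
      ev_idx <- c(ev_idx, sm$fired); ev_t <- c(ev_t, rep(now, length(sm$fired))) }
    if (length(sp$fired)) { ev_mod <- c(ev_mod, rep("perception", length(sp$fired)))
      ev_idx <- c(ev_idx, sp$fired); ev_t <- c(ev_t, rep(now, length(sp$fired))) }

    if (is.na(motor_onset) && length(sm$fired)) {
      motor_onset <- now
      if (reaff) {
        p_on <- step + schedule$total_delay / lif$dt - (lat - 1)
        p_off <- p_on + schedule$reafference_duration / lif$dt - 1
      }
    }
  }
  list(raster = record_raster(ev_mod, ev_idx, ev_t), motor_onset = motor_onset)
}

active_mask <- function(last_spike, now, act_window, dt) {
  a <- !is.na(last_spike) & (now - last_spike) >= dt &
    (now - last_spike) <= act_window
  as.numeric(a)
}

#' Run one action-execution epoch with re-afference
#'
#' The emotion block fires first; its hereditarily wired motor neurons
#' (including SMA, hence M1) follow and keep firing for the scheduled
#' duration; after the 200-ms execution + perception delay the matching
#' percept block fires (re-afference). With `learn = TRUE` the plastic
#' perception-to-motor weights are updated by STDP over the epoch's spike
#' pairs.
#'
#' @param net An [build_network()] object.
#' @param emotion `"pain"` or `"normal"`.
#' @param schedule A [training_schedule()].
#' @param learn Apply STDP at the end of the epoch?
#' @param t0 Absolute time offset (ms) for the raster.
#' @return A list with the updated `net` and the epoch `raster`.
#' @export
run_execution_epoch <- function(net, emotion, schedule = training_schedule(),
                                learn = TRUE, t0 = 0) {
  eidx <- net$spec$emotion_coding[[emotion]]
  if (is.null(eidx)) stop("unknown emotion label: ", emotion)
  percept <- paste0("perceive-", net$spec$overt_actions[[emotion]])
  pidx <- net$spec$perception_coding[[percept]]
  sim <- simulate_network(
    net, duration = schedule$motor_firing_duration + 50,
    emotion_idx = eidx, emotion_window = c(1, schedule$motor_firing_duration),
    percept_idx = pidx, percept_window = "reafference",
    trigger_gate = TRUE, schedule = schedule, t0 = t0)
  if (learn) {
    df <- as.data.frame(sim$raster)
    pre <- df[df$module == "perception", , drop = FALSE]
    post <- df[df$module == "motor", , drop = FALSE]
    net$W_perception_motor <- apply_stdp(net$W_perception_motor,
                                         pre, post, net$stdp)
    net$epochs_trained <- net$epochs_trained + 1L
  }
  list(net = net, raster = sim$raster)
}

#' Train the network over repeated execution + re-afference epochs
#'
#' Runs `schedule$epochs` execution epochs for each listed emotion and
#' records per-epoch summaries of the three plastic synapse classes:
#' inhibitory perception-to-SMA magnitude, perception-to-M1 weight
#' (structurally absent, hence zero), and same-action excitatory
#' perception-to-mirror weight. Optionally probes empathy after every epoch
#' by presenting the percept of the first emotion's overt action alone and
#' testing whether its emotion block activates with M1 silent and no overt
#' action.
#'
#' @param net An untrained or partially trained [build_network()] object.
#' @param emotions Emotion labels to train (default both channels).
#' @param schedule A [training_schedule()].
#' @param probe Run the per-epoch empathy probe? (default `FALSE`).
#' @return A list: `net` (trained), `trajectory` (data frame `epoch`,
#'   `sma_inhibitory`, `m1`, `mirror_excitatory`), and when probed,
#'   `empathy` (logical per epoch) and `empathy_epoch` (first passing epoch,
#'   `NA` if never).
#' @export
train_network <- function(net, emotions = c("pain", "normal"),
                          schedule = training_schedule(), probe = FALSE) {
  traj <- vector("list", schedule$epochs)
  empathy <- logical(schedule$epochs)
  probe_percept <- paste0("perceive-", net$spec$overt_actions[[emotions[1]]])
  epoch_len <- schedule$motor_firing_duration + 50 + schedule$epoch_gap
  t0 <- 0
  if (schedule$epochs >= 1) for (ep in seq_len(schedule$epochs)) {
    for (em in emotions) {
      res <- run_execution_epoch(net, em, schedule, learn = TRUE, t0 = t0)
      net <- res$net
      t0 <- t0 + epoch_len
    }
    traj[[ep]] <- cbind(epoch = ep, weight_summaries(net))
    if (probe) {
      obs <- observe_other(net, probe_percept)
      target_block <- emotions[1]
      empathy[ep] <- obs$emotion_blocks[[target_block]] &&
        !any(obs$emotion_blocks[names(obs$emotion_blocks) != target_block]) &&
        obs$m1_silent && !obs$overt_action_emitted
    }
  }
  out <- list(net = net, trajectory = do.call(rbind, traj))
  if (probe) {
    out$empathy <- empathy
    out$empathy_epoch <- if (any(empathy)) which(empathy)[1] else NA_integer_
  }
  out
}

# Mean plastic weight of the three synapse classes tracked during training.
weight_summaries <- function(net) {
  spec <- net$spec
  mp <- spec$motor_partition
  mi <- motor_indices(spec)
  W <- net$W_perception_motor$weights
  p1 <- spec$perception_coding$`perceive-red`
  p2 <- spec$perception_coding$`perceive-green`
  sma_inh <- mean(c(W[p1, mp$sma1], W[p2, mp$sma2]))
  m1 <- mean(W[, mi$m1])
  mirror <- mean(c(W[p1, c(mp$mirror1, mp$shared_p1, mp$shared_pall)],
                   W[p2, c(mp$mirror2, mp$shared_p2, mp$shared_pall)]))
  data.frame(sma_inhibitory = sma_inh, m1 = m1, mirror_excitatory = mirror)
}

#' Observe another agent's overt action
#'
#' Presents a percept block alone (no emotional trigger): mirror neurons
#' fire through the learned excitatory weights, SMA receives only the
#' learned inhibition and stays silent, hence M1 stays silent, and the
#' emotion block matching the observed action activates through the reverse
#' motor-to-emotion read-out. Because only the mirror subset of the motor
#' module fires, the condition for emitting the overt action is not met:
#' the observer empathizes without changing color.
#'
#' @param net A trained [build_network()] object.
#' @param percept `"perceive-red"`, `"perceive-green"`, or `""` (no input).
#' @param duration Probe duration in ms (default 300).
#' @return A list: `emotion_activation` (spike count per emotion neuron),
#'   `emotion_blocks` (named logicals: is each block active?), `m1_silent`,
#'   `overt_action_emitted` (`FALSE` or the emitted color), `raster`.
#' @export
observe_other <- function(net, percept, duration = 300) {
  if (identical(percept, "") || is.null(percept)) {
    pidx <- NULL
  } else {
    pidx <- net$spec$perception_coding[[percept]]
    if (is.null(pidx)) stop("unknown percept label: ", percept)
  }
  sim <- simulate_network(net, duration,
                          percept_idx = pidx, percept_window = c(1, duration),
                          trigger_gate = FALSE)
  summarize_probe(net, sim$raster)
}

#' Execute an emotional overt action
#'
#' Drives an emotion block under an external emotional trigger: the full
#' hereditarily wired motor pattern fires, including SMA and (through the
#' SMA gate) M1, and the mapped overt action color is emitted.
#'
#' @param net An [build_network()] object.
#' @param emotion `"pain"` or `"normal"`.
#' @param duration Drive duration in ms (default 300).
#' @return A list with `overt_action` (the emitted color, or `FALSE` if the
#'   emission condition is not met) plus the fields of [observe_other()].
#' @export
execute_emotion <- function(net, emotion, duration = 300) {
  eidx <- net$spec$emotion_coding[[emotion]]
  if (is.null(eidx)) stop("unknown emotion label: ", emotion)
  sim <- simulate_network(net, duration,
                          emotion_idx = eidx, emotion_window = c(1, duration),
                          trigger_gate = TRUE)
  out <- summarize_probe(net, sim$raster)
  out$overt_action <- out$overt_action_emitted
  out
}

# Shared post-processing of a probe raster: emotion activation, M1 silence,
# and the overt-action emission rule (>= 90% of an action's wired motor
# neurons, M1 included, must fire within the window).
summarize_probe <- function(net, raster, overt_fraction = 0.9) {
  spec <- net$spec
  mp <- spec$motor_partition
  mi <- motor_indices(spec)
  df <- as.data.frame(raster)
  efires <- df[df$module == "emotion", "neuron_index"]
  activation <- tabulate(efires, nbins = spec$n_emotion)
  blocks <- vapply(spec$emotion_coding, function(idx) any(activation[idx] > 0),
                   logical(1))
  fired_m <- raster_fired(raster, "motor")
  wired <- emotion_wired_motor(spec)
  m1_of <- list(pain = c(mp$m1_from_sma1, mp$m1_from_both),
                normal = c(mp$m1_from_sma2, mp$m1_from_both))
  emitted <- FALSE
  for (em in names(wired)) {
    full <- c(wired[[em]], m1_of[[em]])
    if (mean(full %in% fired_m) >= overt_fraction) {
      emitted <- unname(spec$overt_actions[[em]])
      break
    }
  }
  list(emotion_activation = activation,
       emotion_blocks = blocks,
       m1_silent = !any(mi$m1 %in% fired_m),
       overt_action_emitted = emitted,
       raster = raster)
}

#' Classify motor neurons by their execution/observation response profile
#'
#' Probes every motor neuron under four conditions — executing each of the
#' two trained actions and observing each — and assigns the label matching
#' its binary response profile: pure executors, mirror neurons of one or
#' both actions (including the both-execution variants), and anti-mirror
#' neurons (active in both executions, silent in both observations).
#'
#' @param net A trained [build_network()] object.
#' @param emotions The two trained emotion labels.
#' @param duration Probe duration per condition (ms).
#' @return A list: `profiles` (data frame, one row per motor neuron with
#'   logical columns `exec1`, `exec2`, `obs1`, `obs2` and `type`) and
#'   `census` (data frame of counts per realized profile).
#' @export
classify_neurons <- function(net, emotions = c("pain", "normal"),
                             duration = 300) {
  if (net$epochs_trained == 0L)
    stop("classify_neurons needs a trained network (profiles degenerate)")
  percepts <- paste0("perceive-", net$spec$overt_actions[emotions])
  ex1 <- raster_fired(execute_emotion(net, emotions[1], duration)$raster, "motor")
  ex2 <- raster_fired(execute_emotion(net, emotions[2], duration)$raster, "motor")
  ob1 <- raster_fired(observe_other(net, percepts[1], duration)$raster, "motor")
  ob2 <- raster_fired(observe_other(net, percepts[2], duration)$raster, "motor")
  n <- net$spec$n_motor
  prof <- data.frame(neuron = seq_len(n),
                     exec1 = seq_len(n) %in% ex1, exec2 = seq_len(n) %in% ex2,
                     obs1 = seq_len(n) %in% ob1, obs2 = seq_len(n) %in% ob2)
  prof$type <- mapply(profile_label, prof$exec1, prof$exec2, prof$obs1, prof$obs2)
  census <- aggregate(list(count = prof$neuron),
                      by = prof[, c("exec1", "exec2", "obs1", "obs2", "type")],
                      FUN = length)
  census <- census[order(-census$count, census$type), , drop = FALSE]
  rownames(census) <- NULL
  list(profiles = prof, census = census)
}

profile_label <- function(e1, e2, o1, o2) {
  if (e1 && !e2 && !o1 && !o2) "EXEC-ONLY(1)"
  else if (e1 && !e2 && o1 && !o2) "MN(1)"
  else if (!e1 && e2 && !o1 && !o2) "EXEC-ONLY(2)"
  else if (!e1 && e2 && !o1 && o2) "MN(2)"
  else if (e1 && e2 && o1 && !o2) "MN(1)/EXEC(1,2)"
  else if (e1 && e2 && !o1 && o2) "MN(2)/EXEC(1,2)"
  else if (e1 && e2 && o1 && o2) "MN(1,2)"
  else if (e1 && e2 && !o1 && !o2) "ANTI-MN"
  else if (!e1 && !e2 && !o1 && !o2) "SILENT"
  else "OTHER"
}

#' Infer the emotion behind a motor activation pattern
#'
#' Reads a motor activation vector out through the reverse motor-to-emotion
#' wiring. M1 neurons have no emotion projection, so the read-out of a full
#' execution pattern equals that of its mirror-only subset.
#'
#' @param net An [build_network()] object.
#' @param motor_activation Logical or 0/1 vector of length `n_motor`.
#' @return A list with `drive` (steady input current per emotion neuron)
#'   and `active` (logical: drive exceeds the firing threshold).
#' @export
infer_emotion_from_motor <- function(net, motor_activation) {
  if (length(motor_activation) != net$spec$n_motor)
    stop("motor_activation length must equal n_motor")
  drive <- net$gains$motor_emotion *
    as.numeric(as.numeric(motor_activation) %*% net$W_motor_emotion)
  list(drive = drive, active = drive > net$lif$u_th)
}

#' Write the plastic weight trajectory or final matrix to CSV
#'
#' @param x The `trajectory` data frame from [train_network()] or a trained
#'   network (whose dense final weight grid is written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(x, path) {
  if (inherits(x, "empathy_network")) {
    utils::write.csv(x$W_perception_motor$weights, path, row.names = FALSE)
  } else {
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
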