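test_that("fixed wiring: SMA drives M1, emotion drives its wired motor block", {
  net <- build_network()
  mp <- net$spec$motor_partition
  ex <- execute_emotion(net, "pain")
  fired <- empathysim:::raster_fired(ex$raster, "motor")
  wired <- empathysim:::emotion_wired_motor(net$spec)$pain
  m1_pain <- c(mp$m1_from_sma1, mp$m1_from_both)
  # every hereditarily wired non-M1 neuron and the SMA-gated M1 block fire
  expect_true(all(wired %in% fired))
  expect_true(all(m1_pain %in% fired))
  # the other action's private groups stay silent
  expect_false(any(c(mp$sma2, mp$mirror2, mp$m1_from_sma2) %in% fired))
  # M1 onset follows SMA onset (gate direction)
  expect_gt(empathysim:::raster_onset(ex$raster, "motor", mp$m1_from_sma1),
            empathysim:::raster_onset(ex$raster, "motor", mp$sma1))
})

test_that("plastic weights start near zero and partitions must tile the population", {
  net <- build_network()
  W <- net$W_perception_motor$weights
  mi <- empathysim:::motor_indices(net$spec)
  expect_true(all(W[, mi$mirror] == 0))
  expect_true(all(W[, mi$m1] == 0))
  expect_true(all(W[, mi$sma] == 0.01))
  expect_error(module_spec(n_motor = 49), "sum")
})

test_that("an execution epoch shows the 200 ms motor-to-perception onset lag", {
  net <- build_network()
  r <- run_execution_epoch(net, "pain", training_schedule(), learn = FALSE)$raster
  t_e <- empathysim:::raster_onset(r, "emotion")
  t_m <- empathysim:::raster_onset(r, "motor")
  t_p <- empathysim:::raster_onset(r, "perception")
  expect_lt(t_e, t_m)
  expect_equal(t_p - t_m, 200)
  # re-afference targets the matching percept block only
  pidx <- net$spec$perception_coding[["perceive-red"]]
  expect_true(all(empathysim:::raster_fired(r, "perception") %in% pidx))
})

test_that("learning requires learn = TRUE and potentiates the same-action mirror synapses", {
  net <- build_network()
  frozen <- run_execution_epoch(net, "pain", training_schedule(), learn = FALSE)$net
  expect_equal(frozen$W_perception_motor$weights, net$W_perception_motor$weights)

  learned <- run_execution_epoch(net, "pain", training_schedule(), learn = TRUE)$net
  mp <- net$spec$motor_partition
  p1 <- net$spec$perception_coding[["perceive-red"]]
  before <- net$W_perception_motor$weights
  after <- learned$W_perception_motor$weights
  expect_true(all(after[p1, mp$mirror1] > before[p1, mp$mirror1]))
  expect_true(all(after[p1, mp$sma1] > before[p1, mp$sma1]))
  # structurally absent synapses (onto M1 and the cross-restricted shared
  # group) stay at zero
  expect_true(all(after[, empathysim:::motor_indices(net$spec)$m1] == 0))
  expect_true(all(after[p1, mp$shared_p2] == 0))
  expect_error(run_execution_epoch(net, "joy", training_schedule()), "unknown")
})

test_that("weight trajectories: mirror monotone non-decreasing, M1 pinned, inhibition grows", {
  sch <- training_schedule(epochs = 5)
  res <- train_network(build_network(), schedule = sch)
  tr <- res$trajectory
  expect_equal(nrow(tr), 5)
  expect_true(all(diff(tr$mirror_excitatory) >= 0))
  expect_true(all(diff(tr$sma_inhibitory) >= 0))
  expect_gt(tr$sma_inhibitory[5], tr$sma_inhibitory[1])
  expect_true(all(tr$m1 <= 0.01 * 1))
  # zero epochs: network unchanged
  res0 <- train_network(build_network(), schedule = training_schedule(epochs = 0))
  expect_equal(res0$net$W_perception_motor$weights,
               build_network()$W_perception_motor$weights)
})

test_that("observation drives empathy without overt action; untrained network does not", {
  net <- trained_net_short()
  obs <- observe_other(net, "perceive-red")
  pain_idx <- net$spec$emotion_coding$pain
  expect_true(all(obs$emotion_activation[pain_idx] > 0))
  expect_true(all(obs$emotion_activation[-pain_idx] == 0))
  expect_true(obs$m1_silent)
  expect_false(isTRUE(obs$overt_action_emitted != FALSE))

  # specificity: the green percept activates the normal block only
  obs_g <- observe_other(net, "perceive-green")
  expect_true(obs_g$emotion_blocks[["normal"]])
  expect_false(obs_g$emotion_blocks[["pain"]])

  # empty percept: nothing happens
  silent <- observe_other(net, "")
  expect_true(all(silent$emotion_activation == 0))

  # an untrained network shows no mirror response at all
  raw <- observe_other(build_network(), "perceive-red")
  expect_true(all(raw$emotion_activation == 0))
  expect_equal(nrow(raw$raster[raw$raster$module == "motor", ]), 0)
  expect_error(observe_other(net, "perceive-blue"), "unknown")
})

test_that("execution and observation of the same action differ exactly on SMA and M1", {
  net <- trained_net_short()
  mi <- empathysim:::motor_indices(net$spec)
  mp <- net$spec$motor_partition
  ex <- execute_emotion(net, "pain")
  ob <- observe_other(net, "perceive-red")
  expect_equal(ex$overt_action, "red")
  expect_equal(execute_emotion(net, "normal")$overt_action, "green")
  f_ex <- empathysim:::raster_fired(ex$raster, "motor")
  f_ob <- empathysim:::raster_fired(ob$raster, "motor")
  sma_m1_pain <- c(mp$sma1, mp$m1_from_sma1, mp$m1_from_both)
  expect_true(all(sma_m1_pain %in% f_ex))
  expect_false(any(sma_m1_pain %in% f_ob))
  # the self-other signature: outside SMA and M1 the only differences are
  # the single-percept both-execution mirror groups (which by construction
  # fire in both executions but in only one observation)
  others <- setdiff(seq_len(net$spec$n_motor), c(mi$sma, mi$m1))
  diff_other <- setdiff(intersect(f_ex, others), intersect(f_ob, others))
  expect_setequal(diff_other, mp$shared_p2)
  expect_true(all(intersect(f_ob, others) %in% f_ex))
})

test_that("M1 gating: every M1 spike is preceded by a connected SMA spike", {
  net <- trained_net_short()
  mi <- empathysim:::motor_indices(net$spec)
  for (em in c("pain", "normal")) {
    r <- as.data.frame(run_execution_epoch(net, em, training_schedule(),
                                           learn = FALSE)$raster)
    motor <- r[r$module == "motor", ]
    m1 <- motor[motor$neuron_index %in% mi$m1, ]
    sma_times <- motor$time_ms[motor$neuron_index %in% mi$sma]
    for (t in m1$time_ms) {
      expect_true(any(sma_times < t & sma_times >= t - net$act_window))
    }
  }
})

test_that("the neuron census realizes exactly the eight canonical profiles", {
  net <- trained_net_short()
  res <- classify_neurons(net)
  expect_equal(nrow(res$census), 8)
  expect_equal(sum(res$census$count), net$spec$n_motor)
  cs <- res$census
  # mirror rows fire in the matched execute + observe probes
  mn1 <- cs[cs$type == "MN(1)", ]
  expect_true(mn1$exec1 && mn1$obs1 && !mn1$exec2 && !mn1$obs2)
  mn2 <- cs[cs$type == "MN(2)", ]
  expect_true(mn2$exec2 && mn2$obs2 && !mn2$exec1 && !mn2$obs1)
  # anti-mirror neurons fire during both executions and neither observation
  anti <- cs[cs$type == "ANTI-MN", ]
  expect_true(anti$exec1 && anti$exec2 && !anti$obs1 && !anti$obs2)
  expect_true("MN(1,2)" %in% cs$type)
  expect_true("MN(1)/EXEC(1,2)" %in% cs$type)
  expect_true("MN(2)/EXEC(1,2)" %in% cs$type)
  expect_error(classify_neurons(build_network()), "trained")
})

test_that("reverse read-out infers the emotion behind motor activity, ignoring M1", {
  net <- trained_net_short()
  mp <- net$spec$motor_partition
  n <- net$spec$n_motor
  mirror_only <- seq_len(n) %in% mp$mirror1
  full_exec <- seq_len(n) %in% c(mp$sma1, mp$mirror1, mp$m1_from_sma1, mp$m1_from_both)
  a1 <- infer_emotion_from_motor(net, mirror_only)
  a2 <- infer_emotion_from_motor(net, full_exec)
  pain_idx <- net$spec$emotion_coding$pain
  expect_true(all(a1$active[pain_idx]))
  expect_false(any(a1$active[-pain_idx]))
  expect_equal(a1$active, a2$active)  # M1 contributes no emotion projection
  expect_true(all(infer_emotion_from_motor(net, rep(0, n))$drive == 0))
  expect_error(infer_emotion_from_motor(net, rep(0, n - 1)), "length")
})

test_that("training and simulation are deterministic", {
  sch <- training_schedule(epochs = 2)
  a <- train_network(build_network(), schedule = sch)
  b <- train_network(build_network(), schedule = sch)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$net$W_perception_motor$weights,
                   b$net$W_perception_motor$weights)
  ra <- as.data.frame(observe_other(a$net, "perceive-red")$raster)
  rb <- as.data.frame(observe_other(b$net, "perceive-red")$raster)
  expect_identical(ra, rb)
})
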