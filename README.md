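# empathysim

Affective empathy — being directly affected by, and matching, another's
emotional state — motivates altruistic behavior such as aid-giving. This
package simulates a developmental, neurally grounded account of that
ability for researchers in computational neuroscience and cognitive
robotics, and reproduces its three published results: the emergence of
mirror and anti-mirror neurons in a spiking network, empathy without overt
imitation, and an altruistic rescue learned from purely intrinsic reward.

The model has three parts:

* **Artificial pain as free energy.** The agent continually predicts its
  next body pose (a pentagon with five vertices, grid cell length 25) from
  its own movement rule and scores the outcome as a sum of squared
  prediction errors,
  `FE = Σᵢ (Xᵢᵖʳᵉ − Xᵢᵃᶜᵗ)² + Σᵢ (Yᵢᵖʳᵉ − Yᵢᵃᶜᵗ)²`.
  Motor damage (inverted commands after colliding with a dangerous object)
  makes `FE > 0`, which *is* the pain state; `FE = 0` is the normal state.
* **A three-population spiking network.** Emotion, motor and perception
  modules (40/50/40 leaky integrate-and-fire neurons; `u_th = 60` mV,
  `τ_m = 30` ms, `u_rest = u_reset = 0` mV) with population coding. During
  action execution the motor pattern fires continuously and the matching
  percept arrives 200 ms later (re-afference); spike-timing-dependent
  plasticity (`A⁺ = 0.25`, `A⁻ = 0.01`, `τ± = 10` ms) then wires
  perception onto the motor neurons of the same action, creating mirror
  neurons. SMA neurons receive inhibitory plastic synapses instead and are
  the sole input to M1, so observing another agent's action leaves M1
  silent: execution and observation produce different firing patterns
  (anti-mirror neurons, self–other differentiation).
* **Intrinsic-reward rescue.** An observer empathizes with a trapped,
  damaged explorer through the trained network and learns, by tabular
  Q-learning whose only rewards are its own empathized-pain transitions
  (−1 per pain step, +10 at relief, −0.01 otherwise), to press the switch
  that frees it.

## Worked example

```r
library(empathysim)

cfg <- default_config(seed = 1)
p1 <- run_phase1(cfg)           # exploration + pain sensing + training

subset(p1$fe_trace, event != "")
#>     step fe_raw fe_clipped  pain     event
#> 46    46      0          0 FALSE    switch
#> 117  117      0          0 FALSE collision
#> 122  122  12500       3125  TRUE  recovery
```

The explorer happens to touch the switch at step 46, collides with the
dangerous object at step 117 (the collision move itself is still correctly
predicted, so pain starts on the next step), then flees through the passage
and recovers at step 122 — every damaged step in between scores
`FE = 12500` (two-cell discrepancy, clipped to 3125 in the trace).

```r
p1$trajectory[c(1, 2, 100), ]
#>     epoch sma_inhibitory m1 mirror_excitatory
#> 1       1      0.4079833  0         0.3979833
#> 2       2      0.6443797  0         0.9036638
#> 100   100      1.0000000  0         1.0000000
p1$empathy_epoch
#> [1] 2
```

Mirror and inhibitory weights grow monotonically while perception→M1 stays
at zero; from epoch 2 the red percept alone suffices for empathy:

```r
obs <- observe_other(p1$net, "perceive-red")
obs$emotion_blocks        # pain TRUE, normal FALSE
obs$m1_silent             # TRUE  — no muscle command
obs$overt_action_emitted  # FALSE — feels pain, does not turn red

run_census(p1$net)$census
#>   exec1 exec2  obs1  obs2            type count
#> 1  TRUE FALSE FALSE FALSE    EXEC-ONLY(1)     9
#> 2 FALSE  TRUE FALSE FALSE    EXEC-ONLY(2)     9
#> 3  TRUE  TRUE  TRUE  TRUE         MN(1,2)     6
#> 4  TRUE FALSE  TRUE FALSE           MN(1)     6
#> 5  TRUE  TRUE  TRUE FALSE MN(1)/EXEC(1,2)     6
#> 6 FALSE  TRUE FALSE  TRUE           MN(2)     6
#> 7  TRUE  TRUE FALSE  TRUE MN(2)/EXEC(1,2)     6
#> 8  TRUE  TRUE FALSE FALSE         ANTI-MN     2
```

Eight motor-neuron profiles are realized, including the two anti-mirror
neurons active during both executions and silent during both observations.
Phase 2 then learns the rescue:

```r
p2 <- run_phase2(cfg, p1$net)
c(p2$greedy_steps, p2$shortest_path)   # converged greedy path = BFS shortest
```

A command-line driver with the same functionality (CSV + PNG artifacts)
lives in `inst/cli/`:

```sh
Rscript inst/cli/empathy-experiments.R all --seed 1 --out results/
```

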