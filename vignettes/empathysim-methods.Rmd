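---
title: "Modeling affective empathy: pain from prediction error, mirror neurons from re-afference, altruism from intrinsic reward"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling affective empathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empathysim)
```

## Overview

`empathysim` simulates a developmental account of affective empathy in three
stages, each of which is an independently usable component:

1. **An internal pain state from prediction error.** The agent scores the
   mismatch between the body pose it predicted for its last motor command and
   the pose it actually reached. Under unit-variance Gaussian generative
   assumptions this score is a free energy — a sum of squared prediction
   errors — and any positive value flags the pain (injured) state.
2. **Mirror-neuron emergence from execution + re-afference.** A
   three-population leaky integrate-and-fire (LIF) network — emotion, motor,
   perception — is trained by spike-timing-dependent plasticity (STDP) while
   the agent executes emotional overt actions and, 200 ms later, perceives
   them (re-afference). Perception-to-motor synapses representing the same
   action potentiate, creating motor neurons that fire both when acting and
   when merely observing: mirror neurons. A gating group (SMA, the only
   input to the muscle-command group M1) receives *inhibitory* plastic
   synapses instead, so observation leaves M1 silent: the network fires
   differently for self and other (anti-mirror neurons, primary
   self-other differentiation).
3. **Altruism from intrinsic reward.** In a two-zone grid world, an observer
   watches an explorer collide with a dangerous object and turn red. The
   observer's trained network converts the red percept into empathized pain;
   the relief of that shared pain — obtained by opening a passage that lets
   the explorer escape and recover — is the only reward of a tabular
   Q-learning policy. No task reward is ever specified externally.

## The pain model

The agent's body is a pentagon with five 2D vertices; one grid cell spans 25
coordinate units. After each motor command the agent predicts its next pose
with its *healthy* movement rule (one cell in the commanded direction,
blocked moves included — the agent knows its own movement rule, walls and
all) and compares prediction with outcome:

$$FE = \sum_{i=1}^{5}\left(X^{pre}_i - X^{act}_i\right)^2 +
       \sum_{i=1}^{5}\left(Y^{pre}_i - Y^{act}_i\right)^2 .$$

Colliding with the dangerous object inverts the motor system (commanding
right moves left), so every subsequent move mispredicts: a two-cell
discrepancy scores $5\cdot 50^2 = 12500$, a one-cell discrepancy (inverted
move into a wall) $5\cdot 25^2 = 3125$, and a correct prediction 0. Only the
*sign* of the score matters to the model — pain iff $FE > 0$ — so recorded
traces clip at 3125 purely for display. Two boundary cases follow from the
mechanics rather than from an extra rule: the collision move itself is still
correctly predicted (damage takes effect on the *next* act), so pain starts
one step after the collision; and a healthy agent pressing into a wall
predicts the blocked outcome correctly and feels nothing.

`free_energy_general()` exposes the underlying Gaussian form — the
single-sensor version $\tfrac12[s-g_s(\hat\phi)]^2 +
\tfrac12[\hat\phi-\mu_\phi]^2$ and the split vision/proprioception/dynamics
version — with caller-supplied generator functions, for uses beyond the grid
world (e.g. generators learned by motor babbling on a robot). Learning those
generators is out of scope here.

## The spiking network

**Neuron model.** LIF with $\tau_m \dot u = -(u-u_{rest}) + RI(t)$,
$u_{rest}=u_{reset}=0$ mV, $u_{th}=60$ mV, $\tau_m=30$ ms, explicit Euler at
$dt = 1$ ms (the model's latencies are multiples of 100 ms; 1 ms resolves
spike order). There is no refractory period beyond the reset. All drives —
external and fixed-synaptic — deliver $RI = 2u_{th} = 120$ mV, so a driven
neuron first fires after $\tau_m\ln 2 \approx 21$ ms and then periodically
while the drive lasts. A presynaptic neuron counts as *active* for 25 ms
after a spike (just above one inter-spike interval), which turns spike
trains into sustained synaptic currents without modeling conductances.

**Populations and wiring.** Emotion (40), motor (50), perception (40)
neurons, population-coded: pain = first 20 emotion neurons, normal = last
20; perceive-red / perceive-green likewise split the perception module. The
motor module partition (sizes are configuration, not anatomy — the model
only needs every group to be non-empty) is:

| group | size | drive | role |
|---|---|---|---|
| SMA1 / SMA2 | 5 + 5 | emotion 1 / 2 | action initiation; gate to M1 |
| M1 | 10 | SMA only | muscle command; 4 from SMA1, 4 from SMA2, 2 from both |
| mirror1 / mirror2 | 6 + 6 | emotion 1 / 2 | action-specific mirror candidates |
| shared (3 groups) | 6 + 6 + 6 | both emotions | mirror candidates; plastic input restricted to percept 1, percept 2, or unrestricted |

Fixed ("hereditary") wiring: each emotion block excites every non-M1 motor
neuron wired to it; SMA excites its M1 neurons strongly enough that SMA
activity fires M1 immediately; and a reverse motor-to-emotion read-out maps
the *action-specific* groups (SMA$_k$ and mirror$_k$) back to emotion block
$k$. Three wiring choices deserve explanation because the design space was
genuinely open:

* **Reverse read-out from action-specific groups only.** A symmetric
  (transposed) reverse wiring would let the shared both-action groups
  project to both emotion blocks; counting active inputs shows no firing
  threshold then separates "execution must not activate the other emotion"
  from "observation must activate the matching one". Reading out only from
  groups that carry action identity makes empathy exactly specific.
* **Trigger-gated forward projection.** The emotion-to-motor projection
  transmits only externally triggered emotion activity (the pain-model
  signal). Empathized emotion — driven through the reverse read-out during
  observation — does not re-enter the motor module. Without this gate the
  empathized emotion would re-ignite every emotion-wired motor neuron,
  observation rasters would no longer show only mirror neurons, and the
  eight-profile census below would collapse to six.
* **Structural restriction of plastic input.** Two of the three shared
  mirror groups accept plastic synapses from only one percept block. A
  neuron driven by both emotions fires during both trainings, so
  unrestricted STDP would potentiate both percept blocks onto it; the
  restriction is what allows "responds to both executions but only one
  observation" profiles to exist at all. We read this as a developmental
  connectivity constraint.

**Plasticity.** Pair-based exponential STDP, all pairs within a 50 ms
(5$\tau$) window: $\Delta\omega = A_+e^{\Delta t/\tau_+}$ for pre-before-post,
$-A_-e^{-\Delta t/\tau_-}$ for post-before-pre, $\Delta t = 0$ contributes
nothing. $A_+ = 0.25$, $A_- = 0.01$, $\tau_\pm = 10$ ms; plastic weights
live in $[0, 1]$ and are clamped after each epoch's batch update. Weights
are stored as magnitudes; for the inhibitory perception-to-SMA synapses,
potentiation *grows the magnitude* of the negative-effect weight (they start
at 0.01 so plasticity has a direction to strengthen). The inhibitory gain
(2.5 per unit weight per active input) is deliberately too weak to silence
SMA under the full execution drive ($120 - 50 = 70 > u_{th}$): inhibition
biases execution but only vetoes activity when there is no excitatory drive
at all, i.e. during observation. If it could veto execution, SMA would fall
silent mid-training and the inhibitory weight trajectory would stall and
sawtooth instead of growing monotonically.

**Training.** Each epoch drives one emotion block for 350 ms; the wired
motor pattern (SMA, M1, mirror groups) follows ~21 ms later and keeps
firing; re-afference drives the matching percept block so that perception
onset lags motor onset by *exactly* 200 ms (the scheduler compensates the
21-ms first-spike latency), for 100 ms. Epochs are separated by 300 ms of
silence — longer than both the STDP window and the activity window — so
they are simulated as independent windows with absolute time offsets.
Training runs 100 epochs per emotion by default; both channels (pain/red
and normal/green) are trained so the census over two actions is defined.
In practice the same-action mirror weights cross the empathy threshold
after 2–3 epochs and saturate at the bound shortly after; the 100-epoch
default is the standard schedule, and the per-epoch probe reports the first
epoch at which empathy is actually established.

**Census.** Probing each motor neuron under four conditions (execute /
observe, each action) yields exactly eight realized profiles: pure
executors of each action (SMA and its M1 neurons), action-specific mirror
neurons, both-execution mirror neurons of one or both percepts, and
anti-mirror neurons (the two M1 neurons wired to both SMA groups: active in
both executions, silent in both observations).

## The rescue task

Grid world: 11 × 7 cells, a wall column with one passage cell, dangerous
object at (2, 4), explorer start (4, 4), observer start (7, 2), switch at
(10, 6) on the safety side (in the solo exploration phase the switch sits in
the danger zone instead, so the explorer can free itself — both placements
are configuration). Damage inverts both axes of movement; entering any
safety-zone cell clears it. The explorer random-walks its own zone and, once
damaged *and* the passage is open, follows the shortest route to safety —
the passage opens and the trapped agent leaves immediately.

The observer's policy is tabular Q-learning over (own cell, passage flag) —
the explorer's position is deliberately hidden; only its color percept
reaches the observer, through the same perception module as everything
else. Rewards are purely internal: $-1$ per step of empathized pain,
$+10$ on the step the pain is relieved, $-0.01$ otherwise; only the ordering
matters. The observer acts only while empathized pain is present — the
motivation *is* the shared negative emotion, so an unmotivated observer
rests. This is also why rescue events are correctly ordered (explorer pain
always precedes the switch press). Hyperparameters: $\alpha = 0.1$,
$\gamma = 0.9$, $\varepsilon = 0.1$ decaying by 0.99 per episode (floor
0.01), 300 episodes of at most 200 steps — the smallest standard setting
that converges on this grid; the converged greedy path to the switch equals
the BFS shortest path. The observer's own pose-prediction pain is not part
of the reward (the intrinsic reward is defined over the *empathized*
transition only), and with an untrained network the observer never becomes
motivated, so no rescue policy can emerge — the ablation that separates
"empathy drives altruism" from mere exploration.

## What the simulation does and does not show

All inputs are generated internally; there is no external data. The
generator's defaults *are* the study conditions: the printed neuron and
plasticity constants, the 200 ms re-afference delay, 100 training epochs,
population sizes 40/50/40, grid cell length 25. The world is deterministic
given a seed (the only randomness is the random walk, exploration draws,
and tie-breaks). Passing tests therefore show that the mechanism is
sufficient under these idealized conditions — synchronous population
coding, noise-free percepts, a two-action repertoire, one explorer — not
that it is robust to sensory noise, overlapping population codes, continuous
action spaces, or the richer gating physiology it abstracts. Emotion here
is a two-state flag with a hand-wired motor mapping; hormone-level or
multimodal emotion is out of scope.

## Numerical choices and degenerate inputs

* Explicit Euler at 1 ms; the LIF first-spike latency test is run at `dt`
  and `dt/10` against the closed form.
* Spike pairing is all-pairs within the truncation window; the vectorized
  update is tested against a brute-force nested-loop oracle.
* Coincident spikes ($\Delta t = 0$) change nothing; weights clamp to
  $[0,1]$; structurally absent synapses are pinned at zero.
* Blocked moves predict correctly (no pain from walls); greedy-policy ties
  are broken uniformly at random during learning and by first index in the
  deterministic greedy roll-out.
* Zero training epochs leave the network untouched; probing an untrained
  network for a census or an empathic reward is a contract violation.

## Reproducing the experiments

```{r, eval = FALSE}
cfg <- default_config(seed = 1)
p1 <- run_phase1(cfg, out_dir = "results")   # exploration + training
p1$empathy_epoch                              # first epoch empathy holds
p2 <- run_phase2(cfg, p1$net, out_dir = "results")
p2$greedy_steps == p2$shortest_path           # converged rescue path
run_census(p1$net)$census                     # eight motor profiles
```

The same drivers are exposed as a command-line tool in
`inst/cli/empathy-experiments.R`; `scripts/acceptance.R` recomputes the
headline quantities from scratch and writes them as JSON.
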