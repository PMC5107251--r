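---
title: "A log-odds plasticity model of classical and operant conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A log-odds plasticity model of classical and operant conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condlearn)
```

## The model

`condlearn` simulates associative learning — Pavlovian (classical) and
Thorndike-style (operant) conditioning — with one learning rule. The agent
is a small layered network: working-memory neurons encode the perceived
stimulus, and an action module of one or more layers encodes action chains,
one layer per step of the chain. Non-last-layer neurons are linear
(ADALINE-style, output $u = \mathbf w^\top \mathbf x$); last-layer neurons
are perceptron units that fire when $u \ge b$, with the boundary inclusive.

Every synapse between working memory and the action module (and between
action layers) keeps two tallies: $n_r$, how often the action chain through
it was rewarded, and $\bar n_r$, how often it was not. Its weight is the
log likelihood ratio

$$ w = \ln\frac{n_r}{\bar n_r}. $$

One trial outcome updates the weight incrementally,

$$ w \leftarrow w + \ln\!\Big(1 + \frac{1 + e^{-w}}{n_r + \bar n_r}\Big)
   \quad\text{(rewarded)}, \qquad
   w \leftarrow w - \ln\!\Big(1 + \frac{1 + e^{w}}{n_r + \bar n_r}\Big)
   \quad\text{(unrewarded)}, $$

evaluated at the pre-update totals, after which the matching count is
incremented. Every synapse along the executed chain receives the same
outcome. In the large-count limit $\mu = 1/(n_r + \bar n_r)$ acts as a
shrinking learning rate, $\Delta w = \mu(1 + e^{-w})$ or
$-\mu(1 + e^{w})$, and under Bernoulli reward with probability $p$ the
expected change vanishes exactly at $w = \ln\frac{p}{1-p}$: the weight is a
consistent estimator of the log-odds of reward, which is why learning is
bounded and self-stabilising (`expected_delta()`, `stationary_weight()`).

Reward is produced by a simulated dopaminergic stage. Each perceived state
carries a scalar *ideal degree* (ID) rating how favourable it is, and the
reward for a trial is a sigmoid of the ID change,

$$ R = \frac{2}{1 + e^{-\Delta \mathrm{ID}}} - 1 \in (-1, 1), \qquad
   \delta = k\,(R - R'), $$

with gain $k = 1$ and reward prediction $R' = 0$ by default (the simulated
agents hold no expectations, so $\delta = kR$). A trial is *rewarded* iff
$\delta > 0$; $\Delta \mathrm{ID} = 0$ counts as unrewarded.

Actions are chosen greedily, winner-take-all: at each layer the neuron with
the largest incoming weight from the already-chosen neuron of the previous
layer wins (for the first layer, the linear drive under the current
stimulus, which reduces to the raw input weights for a unit stimulus).
Convergence is tracked by the *system entropy*
$\mathrm{SE} = -\sum_i p_i \ln p_i$, the Shannon entropy of the empirical
sequence-selection distribution $p_i = N_i/N$; a run stops once SE falls
below a threshold, or at the trial cap.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| pseudocounts $n_r = \bar n_r = 1$ | fixed (canonical mode) | makes $w = 0$ before learning and the count-ratio identity exact |
| `se_stop` | 0.3 nats | entropy level at which a run is deemed converged |
| `min_trials_before_stop` | 5 | guard so a reloaded, already-trained agent still executes a few trials |
| `growth_budget` | 30 trials | unrewarded trials at a depth before a layer is added |
| `phase2_trials` | 100 | trial cap of the sequence-learning phase |
| `acquisition_trials`, `extinction_trials` | 50 | Pavlovian phase lengths |
| `k` | 1 | dopamine gain; scales $\delta$ but not the rewarded flag |
| `threshold_b` | grid sweeps | salivation threshold; acquisition sweep 2.5–5.5 by 0.3 (11 values), extinction sweep 1.0–4.3 by 0.3 (12 values) |
| `tie_break` | `"first"` | deterministic lowest-index tie-break; `"random"` draws uniformly among tied maxima |

Entropy is computed in natural log (nats) throughout, and the 0.3 stopping
level is interpreted in nats, for consistency with the model's other
formulas, which are all stated in `ln`.

## The two built-in worlds

**Pavlov.** Two working-memory channels (bell = conditioned stimulus, food
= unconditioned stimulus) feed a single salivation neuron. Food raises the
ideal degree by one unit, so paired trials are rewarded and bell-alone
trials are not; the direction of the ID change is what the scenario fixes,
and its magnitude only scales $\delta$, never the rewarded flag. In
canonical mode the bell weight after $t$ paired trials is exactly
$\ln(1+t)$ — concave and strictly increasing — and after $t$ extinction
trials from a 50-trial acquisition store it is $\ln\!\frac{51}{1+t}$,
strictly decreasing with slowing speed. The salivation response to the bell
alone appears earlier for smaller thresholds $b$ and extinguishes earlier
for larger $b$; both orderings are asserted in the test suite. A
Rescorla–Wagner trajectory ($\Delta V = \alpha(\lambda - V)$,
$\alpha = 0.1$) is provided as the classical baseline; the comparison is
qualitative — a connective weight and an associative value share no common
scale.

**Thorndike.** One working-memory neuron codes the satiety state 1–3
(hungry, half-hungry, full), which is also the state's ideal degree. The
action module starts with one layer of two actions, `a1` (north) and `a2`
(east); the puzzle-box state machine rewards only the chain `a1a2`.
Single-action transitions never improve the state, so phase 1 is thirty
unrewarded trials during which the two input weights decay alternately
(winner-take-all plus first-index ties make the agent alternate). The
growth budget then adds a second layer, and in phase 2 the agent errs
twice (`a1a1`, then `a2a1`), discovers `a1a2` at trial 3 and repeats it
until the cumulative-count entropy crosses 0.3 — at trial 29, given exactly
two early errors. With long-term persistence (`run_repeated_thorndike()`),
later runs reload the trained network and stop after the minimum-trial
guard, so trials-to-stop is non-increasing across runs: a trial-count
analogue of the law of exercise (the original escape-time curve depends on
hardware timing, which is out of scope here).

The transition table's two-action rows are authoritative; they are *not*
the composition of its single-action rows (from the full state, `a2a1`
lands on half-hungry directly, composing the singles would not). Unlisted
sequences (`a1a1`, `a2a2`, longer chains) are evaluated by composing the
single-action rows left to right, which matches the listed behaviour of the
first trial of the sequence phase.

## Design choices where the design was open

* **Pseudocount initialization.** The incremental update divides by
  $n_r + \bar n_r$, which is 0 before any learning if counts start at 0.
  Starting both counts at 1 gives $w = \ln(1/1) = 0$ — the stated "all
  weights start at 0" — and makes the closed count-ratio form and the
  incremental form coincide exactly at every step (audited to $10^{-9}$).
  A `"raw"` mode (counts from 0, outcome count incremented first,
  denominator floored at 1) is provided for sensitivity checks, and an
  `"asymptotic"` mode runs the fixed-$\mu$ limit form.
* **Update order.** The increment is computed from the *pre*-update counts
  and weight, then the count is incremented; this is the unique order under
  which the two forms of the update agree.
* **Selection uses raw weights.** Intermediate layers are pass-through for
  selection: the chain is chosen greedily layer by layer on the stored
  weights, and only the last layer applies the threshold nonlinearity. The
  linear outputs of intermediate neurons are exposed (`linear_output()`)
  but do not gate the choice.
* **Growth appends.** A new layer is appended after the current last layer
  (a longer chain), with one neuron per selectable action and fresh
  pseudocount synapses; existing synapses are never touched. Growth fires
  only if *no* reward has ever been seen at the current depth, and a
  `max_layers` cap (default 2, the depth the puzzle-box task needs)
  prevents unbounded growth in a world that never rewards.
* **Entropy bookkeeping.** Selection statistics are kept over whole
  executed sequences; at depth 1 sequences degenerate to single actions.
  The statistics reset when the network grows (the identity space changes)
  and at the start of each run, while learned weights persist through the
  long-term store. The count-based entropy of the very first selection is
  trivially 0, which is exactly why the `min_trials_before_stop` guard
  exists.
* **Satiety persistence.** By default every puzzle-box trial starts hungry;
  with `persist_state = TRUE` satiety carries over, the state saturates at
  full, the rewarded chain stops paying, and its weights decay until
  behaviour (and reward) resumes — a satiety cycle the tests document.
* **Extinction initialization.** Extinction continues from the acquisition
  long-term store when one is given; otherwise explicit initial counts must
  be supplied (extinction without prior learning is an error).

## What the simulations do and do not show

The built-in worlds are faithful to the *contingencies* of the two classic
experiments — which stimulus predicts reward, which chain opens the box —
but not to their physical realisation: there is no sensor noise, no motor
timing, no spatial kinematics, and trials are abstract sequence executions.
Deterministic first-index tie-breaking reproduces a single canonical
trial-by-trial narrative; the seeded random tie-break shows the same
qualitative behaviour distributionally. Consequently, passing tests
demonstrate the internal consistency of the learning rule and its
convergence properties, not robustness to the noise of embodied data.

Problem sizes are the scenario defaults throughout: 50-trial Pavlov phases,
a 30-trial single-action phase, a 100-trial sequence phase, 10-run
persistence series, and 20,000-step Bernoulli recovery studies over 20
replicates — all desk-scale.

## Known limitations

* Reward attribution is uniform along the chain; there is no credit
  assignment within a sequence (no eligibility traces or temporal-difference
  errors), so an unrewarded chain penalises even its "correct" prefix.
* The reward prediction $R'$ is fixed at 0; the general prediction-error
  form is implemented but no prediction is ever learned.
* Winner-take-all with first-index ties is purely exploitative; exploration
  arises only from tie randomisation and weight decay, not from any
  explicit exploration bonus.
* The log-odds weight estimates a stationary reward probability; the rule
  tracks drifting contingencies only through the shrinking learning rate,
  ever more slowly as counts accumulate.
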