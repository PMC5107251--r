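# condlearn

Simulation of associative learning — Pavlovian (classical) and
Thorndike-style (operant) conditioning — unified under a single
neuromodulated plasticity rule, for computational-neuroscience and
cognitive-modelling work that needs a small, fully inspectable
conditioning agent.

## The model in brief

Each plastic synapse between working memory and a layered winner-take-all
action module tallies how often the action chain through it was rewarded
(*n<sub>r</sub>*) and not rewarded (*n̄<sub>r</sub>*), and carries the
log likelihood ratio weight

&nbsp;&nbsp;&nbsp;&nbsp;*w* = ln(*n<sub>r</sub>* / *n̄<sub>r</sub>*),

updated incrementally by
*w* ← *w* + ln(1 + (1 + e<sup>−w</sup>)/(*n<sub>r</sub>* + *n̄<sub>r</sub>*))
on reward and the mirrored decrement otherwise. Reward comes from a
simulated dopaminergic stage: every perceived state has a scalar *ideal
degree* (ID), the reward is the sigmoid
*R* = 2/(1 + e<sup>−ΔID</sup>) − 1 of the ID change, and the dopamine
signal is δ = k·R (gain k = 1, no reward prediction). A trial is rewarded
iff δ > 0. Under Bernoulli reward with probability *p* the weight
converges to the log-odds ln(*p*/(1−*p*)), so learning is bounded and
self-stabilising; convergence of behaviour is tracked by the system
entropy SE = −Σ *p<sub>i</sub>* ln *p<sub>i</sub>* of the empirical
sequence-selection distribution.

Two worlds are built in: a Pavlovian bell/food scheduler (acquisition and
extinction of a conditioned salivation response, with a
threshold-sensitivity sweep and a Rescorla–Wagner baseline) and a
Thorndike puzzle-box state machine (only the chain `a1a2` — north then
east — is rewarded; the network grows a second action layer when single
actions never pay off, and long-term memory persists learning across
runs). See the vignette in `vignettes/conditioning-model.Rmd` for the full
account.

## Worked example

```r
library(condlearn)

## Pavlovian acquisition: bell and food paired for 50 trials
log <- run_acquisition(run_config("pavlov"))
head(log$trials[, c("trial", "w_bell_salivate", "u_probe", "out_b2.5", "out_b3.7")], 4)
#>   trial w_bell_salivate   u_probe out_b2.5 out_b3.7
#> 1     1       0.6931472 0.6931472        0        0
#> 2     2       1.0986123 1.0986123        0        0
#> 3     3       1.3862944 1.3862944        0        0
#> 4     4       1.6094379 1.6094379        0        0
```

The bell→salivation weight is exactly ln(1 + t) after t paired trials
(ln 2 = 0.693 after the first), the `u_probe` column is the drive the bell
alone produces, and the `out_b*` columns report whether the salivation
neuron would fire at each threshold — with b = 2.5 the conditioned
response to the bell alone appears at trial 12 (ln 13 > 2.5), later for
bigger thresholds.

```r
## Thorndike puzzle box: 30 single-action trials, growth, then sequences
tlog <- run_thorndike(run_config("thorndike"))
tlog
#> <trial_log> thorndike: 59 trial(s)
#>    trial phase sequence state_after     delta rewarded  w_wm1_a1 ...
#> 59    59     2     a1a2           2 0.4621172     TRUE 0.4989912 ...
#>           SE event
#> 59 0.2987581  stop

run_repeated_thorndike(run_config("thorndike"), n_runs = 5)$trials_to_stop
#> [1] 59  5  5  5  5
```

The full run takes 59 trials: 30 unrewarded single-action trials (the two
weights decay alternately), then a second layer is added and the agent
errs twice (`a1a1`, `a2a1`), finds `a1a2` at the third sequence trial
(dopamine δ = 0.462, the sigmoid of a one-step ID improvement) and repeats
it until the selection entropy drops below 0.3 nats at sequence trial 29.
With long-term memory persisted between runs, every later run reloads the
trained network and stops after the 5-trial minimum — practice makes the
task faster.

A thin command-line wrapper over the same functions is installed at
`inst/cli/condlearn`:

```sh
Rscript inst/cli/condlearn thorndike --seed 1 --ltm /tmp/ltm.json --out /tmp/run
```

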