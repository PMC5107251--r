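# End-to-end conditioning experiments.
#
# run_acquisition / run_extinction reproduce the Pavlovian runs: the
# bell-and-food network has two working-memory neurons feeding one
# salivation neuron, whose weights are updated as rewarded on every paired
# trial (acquisition) and as unrewarded on every bell-alone trial
# (extinction).  run_thorndike reproduces the puzzle-box runs: a one-neuron
# working memory (the satiety state) feeds a winner-take-all action module
# that grows from one to two layers when single actions never pay off.

fresh_pavlov_network <- function(cfg) {
  action_network(2, "salivate", wm_labels = c("bell", "food"),
                 threshold_b = cfg$b_grid_acquisition[1],
                 mode = cfg$update_mode)
}

sweep_columns <- function(df, grid) {
  for (b in grid) {
    df[[paste0("out_b", format(b))]] <- threshold_output(df$u_probe, b)
  }
  df
}

run_pavlov_phase <- function(cfg, net, tallies, us_present, grid) {
  n <- if (us_present) cfg$acquisition_trials else cfg$extinction_trials
  rows <- vector("list", n)
  rec <- selection_record()
  for (t in seq_len(n)) {
    step <- pavlov_step(pavlov_trial(TRUE, us_present), cfg$dopamine)
    net <- update_chain(net, 1L, step$rewarded, mu = cfg$mu)
    tallies <- tally_update(tallies, "salivate", step$rewarded)
    rec <- update_probabilities(rec, "salivate")
    se <- system_entropy(selection_probs(rec))
    # probe: drive of the salivation neuron under the bell alone
    u <- linear_output(net$banks[[1]]$w[, 1], c(1, 0))
    rows[[t]] <- data.frame(trial = t, sequence = "salivate",
                            delta = step$delta, rewarded = step$rewarded,
                            t(flatten_weights(net)), u_probe = u, SE = se,
                            event = "", check.names = FALSE)
  }
  df <- sweep_columns(do.call(rbind, rows), grid)
  rownames(df) <- NULL
  if (!is.null(cfg$ltm)) {
    save_long_term(list(network = net, tallies = tallies,
                        meta = list(seed = cfg$seed, trials = n)), cfg$ltm)
  }
  new_trial_log(df, cfg)
}

#' Run the Pavlovian acquisition experiment
#'
#' Bell and food are presented together on every one of
#' `cfg$acquisition_trials` trials, so every trial is rewarded and both
#' input weights grow; in canonical mode the bell weight after trial t is
#' exactly `ln(1 + t)`.  Each trial also logs the bell-alone probe drive
#' `u_probe` and, for every threshold in `cfg$b_grid_acquisition`, whether
#' the salivation neuron would fire to the bell alone (`out_b*` columns).
#'
#' @param cfg A [run_config()] with `env = "pavlov"`.  If `cfg$ltm` is set,
#'   the learned state is loaded from / saved to that long-term store.
#' @return A `trial_log`; `$trials` has one row per trial with the weights
#'   (`w_bell_salivate`, `w_food_salivate`), dopamine `delta`, `u_probe`,
#'   selection entropy `SE` and the threshold-sweep outputs.
#' @export
run_acquisition <- function(cfg = run_config("pavlov")) {
  stopifnot(cfg$env == "pavlov")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  st <- if (!is.null(cfg$ltm)) load_long_term(cfg$ltm) else NULL
  net <- st$network %||% fresh_pavlov_network(cfg)
  run_pavlov_phase(cfg, net, st$tallies %||% list(), us_present = TRUE,
                   grid = cfg$b_grid_acquisition)
}

#' Run the Pavlovian extinction experiment
#'
#' The bell is presented alone on every one of `cfg$extinction_trials`
#' trials, so no trial is rewarded and both weights shrink.  Extinction
#' requires prior learning: the initial weights come from the long-term
#' store at `cfg$ltm` (typically written by [run_acquisition()]) or from
#' `cfg$initial_counts`; with neither, an error is raised.
#'
#' @param cfg A [run_config()] with `env = "pavlov"`.
#' @return A `trial_log` in the same shape as [run_acquisition()]'s, with
#'   the sweep over `cfg$b_grid_extinction`.
#' @export
run_extinction <- function(cfg = run_config("pavlov")) {
  stopifnot(cfg$env == "pavlov")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  st <- if (!is.null(cfg$ltm)) load_long_term(cfg$ltm) else NULL
  if (is.null(st) && is.null(cfg$initial_counts)) {
    stop("extinction requires prior learning: provide cfg$ltm (an existing ",
         "store) or cfg$initial_counts", call. = FALSE)
  }
  if (!is.null(st)) {
    net <- st$network
  } else {
    ic <- cfg$initial_counts
    stopifnot(all(c("bell", "food") %in% names(ic)))
    net <- fresh_pavlov_network(cfg)
    for (j in 1:2) {
      nm <- net$wm_labels[j]
      net$banks[[1]]$nr[j, 1] <- ic[[nm]][1]
      net$banks[[1]]$nbar[j, 1] <- ic[[nm]][2]
      net$banks[[1]]$w[j, 1] <- log(ic[[nm]][1] / ic[[nm]][2])
    }
    net <- validate_action_network(net)
  }
  run_pavlov_phase(cfg, net, st$tallies %||% list(), us_present = FALSE,
                   grid = cfg$b_grid_extinction)
}

#' Run the Thorndike puzzle-box experiment
#'
#' Every trial starts with the agent hungry (state 1).  A full run has two
#' phases.  In the single-action phase the one-layer network picks `a1` or
#' `a2`; neither improves the state, so every trial is unrewarded, the two
#' input weights decay alternately and, once the growth budget
#' (`cfg$policy$growth_budget`, default 30 trials) is exhausted without any
#' reward, a second layer is added.  In the sequence-learning phase the
#' two-layer network picks length-2 chains; only `a1a2` is rewarded, and the
#' run ends when the system entropy of the cumulative sequence-selection
#' counts falls below `cfg$policy$se_stop` (after the minimum trial guard)
#' or the phase cap `cfg$phase2_trials` is hit.
#'
#' Every trial starts from the hungry state unless
#' `cfg$persist_state = TRUE`, in which case satiety carries over and a
#' well-fed agent stops being rewarded (the state code saturates at 3).
#'
#' With `cfg$phase1_trials = 0` the single-action phase is skipped and a
#' fresh run starts directly with a two-layer, zero-weight network.  If
#' `cfg$ltm` names an existing store, the learned network (including its
#' depth) is restored from it and the run continues from that experience;
#' the final state is saved back.
#'
#' @param cfg A [run_config()] with `env = "thorndike"`.
#' @return A `trial_log`; `$trials` has columns `trial`, `phase` (network
#'   depth at selection), `sequence` (e.g. `"a1a2"`), `state_after`,
#'   `delta`, `rewarded`, all weights, `SE` and `event`
#'   (`"grow"`/`"stop"`).
#' @export
run_thorndike <- function(cfg = run_config("thorndike")) {
  stopifnot(cfg$env == "thorndike")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  st <- if (!is.null(cfg$ltm)) load_long_term(cfg$ltm) else NULL
  net <- st$network %||% action_network(1, c("a1", "a2"), wm_labels = "wm1",
                                        threshold_b = -Inf,
                                        mode = cfg$update_mode)
  tallies <- st$tallies %||% list()
  if (cfg$phase1_trials == 0 && length(net$banks) == 1) {
    net <- add_layer(net, length(net$layers[[1]]))
  }
  pol <- cfg$policy
  rec <- selection_record()
  depth_trial <- 0L
  unrewarded <- 0L
  reward_seen <- FALSE
  rows <- list()
  total <- 0L
  state <- 1L  # hungry
  repeat {
    total <- total + 1L
    depth_trial <- depth_trial + 1L
    depth <- length(net$banks)
    state0 <- if (cfg$persist_state) state else 1L
    x <- encode_stimulus(state0, "thorndike")
    idx <- select_sequence(net, x, pol)
    acts <- vapply(seq_along(idx),
                   function(L) net$layers[[L]][idx[L]], character(1))
    id <- paste(acts, collapse = "")
    state1 <- thorndike_transition(state0, acts)
    state <- state1
    rw <- thorndike_reward(state0, state1, cfg$dopamine)
    net <- update_chain(net, idx, rw$rewarded, mu = cfg$mu)
    tallies <- tally_update(tallies, id, rw$rewarded)
    rec <- update_probabilities(rec, id)
    se <- system_entropy(selection_probs(rec))
    if (rw$rewarded) {
      reward_seen <- TRUE
      unrewarded <- 0L
    } else {
      unrewarded <- unrewarded + 1L
    }
    event <- ""
    stop_now <- FALSE
    max_here <- if (depth == 1L) cfg$phase1_trials else cfg$phase2_trials
    if (depth < cfg$max_layers && should_grow(unrewarded, pol, reward_seen)) {
      net <- add_layer(net, length(net$layers[[1]]))
      event <- "grow"
      # new identity space at the new depth: reset the selection statistics
      rec <- selection_record()
      depth_trial <- 0L
      unrewarded <- 0L
      reward_seen <- FALSE
    } else if (should_stop(se, depth_trial,
                           modifyList(pol, list(max_trials = max_here)))) {
      event <- "stop"
      stop_now <- TRUE
    }
    rows[[total]] <- c(list(trial = total, phase = depth, sequence = id,
                            state_after = state1, delta = rw$delta,
                            rewarded = rw$rewarded),
                       as.list(flatten_weights(net)),
                       list(SE = se, event = event))
    if (stop_now) break
  }
  # the weight set widens when the network grows: align rows on the union
  all_nm <- Reduce(union, lapply(rows, names))
  df <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(all_nm, names(r))
    r[miss] <- NA
    as.data.frame(r[all_nm], check.names = FALSE)
  }))
  rownames(df) <- NULL
  if (!is.null(cfg$ltm)) {
    save_long_term(list(network = net, tallies = tallies,
                        meta = list(seed = cfg$seed, trials = total)),
                   cfg$ltm)
  }
  new_trial_log(df, cfg)
}

#' Repeated Thorndike runs with long-term memory persistence
#'
#' Runs the puzzle-box experiment `n_runs` times, saving the learned state
#' to the long-term store after each run and reloading it at the start of
#' the next, and records how many trials each run needs before the entropy
#' stopping rule ends it.  With persistence the later runs start with a
#' trained two-layer network, so the trials-to-stop sequence is
#' non-increasing — practice makes the task faster.
#'
#' @param cfg A [run_config()] with `env = "thorndike"`.  `cfg$ltm` is the
#'   persistence path (a temporary file if `NULL`); `cfg$seed` seeds the
#'   whole series once.
#' @param n_runs Number of successive runs (at least 2).
#' @return List with `trials_to_stop` (integer vector) and `logs` (one
#'   `trial_log` per run).
#' @export
run_repeated_thorndike <- function(cfg = run_config("thorndike"), n_runs = 10) {
  stopifnot(n_runs >= 2)
  if (is.null(cfg$ltm)) cfg$ltm <- tempfile("condlearn-ltm-", fileext = ".json")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg$seed <- NULL  # one RNG stream across the whole series
  logs <- vector("list", n_runs)
  trials <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    logs[[r]] <- run_thorndike(cfg)
    trials[r] <- nrow(logs[[r]]$trials)
  }
  list(trials_to_stop = trials, logs = logs)
}

#' Rescorla-Wagner baseline trajectory
#'
#' The classic error-correction model of conditioning,
#' `V_{t+1} = V_t + alpha * (lambda - V_t)`, used as the comparison baseline
#' for the acquisition (`lambda = 1, V_0 = 0`) and extinction
#' (`lambda = 0, V_0 = 1`) curves.
#'
#' @param trials Number of trials.
#' @param alpha Learning rate in (0, 1] (default 0.1).
#' @param lam Asymptote `lambda`.
#' @param v0 Initial associative value `V_0`.
#' @return Numeric vector of length `trials + 1`: `V_0, V_1, ..., V_trials`.
#' @export
rescorla_wagner <- function(trials, alpha = 0.1, lam = 1, v0 = 0) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  stopifnot(trials >= 0)
  v <- numeric(trials + 1)
  v[1] <- v0
  for (t in seq_len(trials)) v[t + 1] <- v[t] + alpha * (lam - v[t])
  v
}
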