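# Winner-take-all selection, selection statistics and system entropy.

#' Selection / stopping / growth policy
#'
#' @param tie_break `"first"` (deterministic lowest index, the default) or
#'   `"random"` (uniform among tied maxima, drawn from the session RNG so a
#'   seed makes it reproducible).
#' @param min_trials_before_stop Entropy stopping is only consulted from
#'   this trial on, so a run reloaded from a trained long-term store still
#'   executes a few trials instead of halting immediately.
#' @param se_stop Entropy threshold, in nats: stop once `SE < se_stop`
#'   (default 0.3).  Setting 0 disables entropy stopping.
#' @param max_trials Hard per-phase trial cap (default 100).
#' @param growth_budget Number of consecutive unrewarded trials at a given
#'   network depth before a layer is added (default 30).
#' @return A list of class `policy_config`.
#' @export
policy_config <- function(tie_break = c("first", "random"),
                          min_trials_before_stop = 5L,
                          se_stop = 0.3,
                          max_trials = 100L,
                          growth_budget = 30L) {
  tie_break <- match.arg(tie_break)
  if (se_stop < 0) stop("se_stop must be >= 0", call. = FALSE)
  structure(list(tie_break = tie_break,
                 min_trials_before_stop = as.integer(min_trials_before_stop),
                 se_stop = se_stop,
                 max_trials = as.integer(max_trials),
                 growth_budget = as.integer(growth_budget)),
            class = "policy_config")
}

#' Winner-take-all action choice
#'
#' Returns the index of the maximum weight; exact ties go to the lowest
#' index (`"first"`) or to a uniform random tied index (`"random"`).
#'
#' @param weights Non-empty numeric vector of candidate weights.
#' @param cfg A [policy_config()].
#' @return The chosen index.
#' @export
select_action <- function(weights, cfg = policy_config()) {
  if (length(weights) == 0) stop("empty weight vector", call. = FALSE)
  idx <- which(weights == max(weights))
  if (cfg$tie_break == "first" || length(idx) == 1L) {
    idx[1L]
  } else {
    idx[sample.int(length(idx), 1L)]
  }
}

#' Greedy winner-take-all choice of a whole action chain
#'
#' Layer 1 candidates are the linear drives of the first-layer neurons under
#' the stimulus (for a single working-memory neuron with unit output these
#' are the raw input weights); layer L candidates are the raw interlayer
#' weights out of the neuron chosen at layer L-1.
#'
#' @param net An [action_network()].
#' @param stimulus Numeric working-memory output vector, length `net$n_wm`.
#' @param cfg A [policy_config()].
#' @return Integer vector of chosen neuron indices, one per layer.
#' @export
select_sequence <- function(net, stimulus, cfg = policy_config()) {
  if (length(stimulus) != net$n_wm) {
    stop("stimulus length must equal the number of working-memory neurons",
         call. = FALSE)
  }
  out <- integer(length(net$banks))
  cand <- drop(matrix(stimulus, 1) %*% net$banks[[1]]$w)
  out[1] <- select_action(cand, cfg)
  for (L in seq_along(net$banks)[-1]) {
    out[L] <- select_action(net$banks[[L]]$w[out[L - 1], ], cfg)
  }
  out
}

#' Selection statistics over action-sequence identities
#'
#' Tracks how many times each sequence identity has been chosen (`N_i`),
#' from which selection probabilities `p_i = N_i / N` and the system entropy
#' are computed.
#'
#' @return An empty `selection_record`.
#' @export
selection_record <- function() {
  structure(list(counts = integer(0)), class = "selection_record")
}

#' @export
print.selection_record <- function(x, ...) {
  cat("<selection_record>", sum(x$counts), "selections over",
      length(x$counts), "identities\n")
  invisible(x)
}

#' Record one selection and refresh the probabilities
#'
#' @param rec A [selection_record()].
#' @param chosen Sequence identity (character), e.g. `"a1a2"`.
#' @return The updated record.
#' @export
update_probabilities <- function(rec, chosen) {
  stopifnot(is.character(chosen), length(chosen) == 1)
  if (is.na(match(chosen, names(rec$counts)))) {
    rec$counts[chosen] <- 0L
  }
  rec$counts[chosen] <- rec$counts[chosen] + 1L
  rec
}

#' Selection probabilities `p_i = N_i / N`
#'
#' @param rec A [selection_record()].
#' @return Named numeric vector summing to 1 (empty if nothing recorded).
#' @export
selection_probs <- function(rec) {
  n <- sum(rec$counts)
  if (n == 0) return(numeric(0))
  rec$counts / n
}

#' System entropy
#'
#' Shannon entropy `-sum p_i ln p_i` (natural log, nats) of the selection
#' distribution, with `0 ln 0 = 0`.  It measures how far the agent is from
#' settling on a single action sequence; 0 means fully converged.
#'
#' @param probs Probability vector summing to 1 (tolerance 1e-9).
#' @return Entropy in nats.
#' @export
system_entropy <- function(probs) {
  if (any(probs < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (length(probs) && abs(sum(probs) - 1) > 1e-9) {
    stop("probabilities must sum to 1", call. = FALSE)
  }
  p <- probs[probs > 0]
  -sum(p * log(p)) + 0  # + 0 normalizes the signed zero of -sum()

}

#' Entropy / trial-cap stopping rule
#'
#' @param se Current system entropy (nats).
#' @param trial Trial index within the current phase.
#' @param cfg A [policy_config()].
#' @return `TRUE` when learning should end: the entropy has fallen below
#'   `se_stop` (after the minimum number of trials) or the trial cap is hit.
#' @export
should_stop <- function(se, trial, cfg = policy_config()) {
  (trial >= cfg$min_trials_before_stop && se < cfg$se_stop) ||
    trial >= cfg$max_trials
}

#' Layer-growth trigger
#'
#' A layer is added when the growth budget of unrewarded trials is exhausted
#' and no reward has ever been observed at the current network depth.
#'
#' @param unrewarded_trials Consecutive unrewarded trials at this depth.
#' @param cfg A [policy_config()].
#' @param reward_seen Has any reward been observed at this depth?
#' @return Logical.
#' @export
should_grow <- function(unrewarded_trials, cfg = policy_config(),
                        reward_seen = FALSE) {
  !reward_seen && unrewarded_trials >= cfg$growth_budget
}
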