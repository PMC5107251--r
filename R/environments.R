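# The two built-in worlds: a Pavlovian CS/US trial scheduler and the
# Thorndike puzzle-box state machine.

# single-action state transitions; rows = state 1..3, cols = a1, a2
.thorndike_single <- matrix(c(1, 1, 2,   # a1: from states 1, 2, 3
                              1, 1, 2),  # a2
                            nrow = 3, dimnames = list(NULL, c("a1", "a2")))
# listed two-action rows; only a1a2 (press pedal then lift latch analogue,
# i.e. north then east) improves the state
.thorndike_pairs <- matrix(c(2, 3, 3,    # a1a2
                             1, 1, 2),   # a2a1
                           nrow = 3, dimnames = list(NULL, c("a1a2", "a2a1")))

#' Thorndike puzzle-box transition table
#'
#' The discrete state machine of the operant-conditioning world: states 1-3
#' are hungry, half-hungry and full; actions are `a1` (move north) and `a2`
#' (move east).  Only the chain `a1a2` from a non-full state improves the
#' state.
#'
#' @return A data.frame with one row per state and one column per listed
#'   action sequence (`a1`, `a2`, `a1a2`, `a2a1`).
#' @export
thorndike_table <- function() {
  data.frame(state = 1:3,
             a1 = .thorndike_single[, "a1"],
             a2 = .thorndike_single[, "a2"],
             a1a2 = .thorndike_pairs[, "a1a2"],
             a2a1 = .thorndike_pairs[, "a2a1"])
}

#' State transition for an action sequence
#'
#' Listed sequences (single actions and the two-action chains `a1a2`,
#' `a2a1`) are looked up directly in the transition table; unlisted
#' sequences (`a1a1`, `a2a2`, length three or more) are evaluated by
#' composing the single-action rows left to right.
#'
#' @param state Integer state in 1..3.
#' @param seq Character vector of actions in `c("a1", "a2")`, e.g.
#'   `c("a1", "a2")`.
#' @return The resulting state.
#' @export
thorndike_transition <- function(state, seq) {
  if (length(state) != 1 || !state %in% 1:3) {
    stop("state must be one of 1, 2, 3", call. = FALSE)
  }
  if (length(seq) < 1 || !all(seq %in% c("a1", "a2"))) {
    stop("actions must be 'a1' or 'a2'", call. = FALSE)
  }
  key <- paste(seq, collapse = "")
  if (length(seq) == 1) {
    unname(.thorndike_single[state, seq])
  } else if (key %in% colnames(.thorndike_pairs)) {
    unname(.thorndike_pairs[state, key])
  } else {
    for (a in seq) state <- .thorndike_single[state, a]
    unname(state)
  }
}

#' Dopamine outcome of a Thorndike state change
#'
#' The ideal degree of each state is its working-memory code (1, 2 or 3),
#' so the ideal-degree change is simply `state_after - state_before`; the
#' reward and dopamine signals follow from [reward_signal()] and
#' [dopamine()], and the trial is rewarded iff the dopamine signal is
#' strictly positive.
#'
#' @param state_before,state_after Integer states in 1..3.
#' @param cfg A [dopamine_config()].
#' @return List with `delta` (dopamine value) and `rewarded` (logical).
#' @export
thorndike_reward <- function(state_before, state_after,
                             cfg = dopamine_config()) {
  stopifnot(state_before %in% 1:3, state_after %in% 1:3)
  d <- dopamine(reward_signal(state_before, state_after), cfg)
  list(delta = d, rewarded = is_rewarded(d))
}

#' One Pavlovian trial specification
#'
#' @param cs_present Is the conditioned stimulus (bell) presented?
#' @param us_present Is the unconditioned stimulus (food) presented?
#' @return A list of class `pavlov_trial`.
#' @export
pavlov_trial <- function(cs_present, us_present) {
  structure(list(cs_present = isTRUE(cs_present),
                 us_present = isTRUE(us_present)),
            class = "pavlov_trial")
}

#' Execute one Pavlovian trial
#'
#' Food raises the perceived state's ideal degree by one unit, so the trial
#' is rewarded exactly when the unconditioned stimulus is present; the bell
#' alone leaves the ideal degree unchanged (dopamine 0, unrewarded).
#'
#' @param spec A [pavlov_trial()].
#' @param cfg A [dopamine_config()].
#' @return List with `stimulus` (named binary vector over the `bell` and
#'   `food` channels), `delta` (dopamine) and `rewarded`.
#' @export
pavlov_step <- function(spec, cfg = dopamine_config()) {
  stopifnot(inherits(spec, "pavlov_trial"))
  stim <- encode_stimulus(list(bell = spec$cs_present, food = spec$us_present),
                          "pavlov")
  d_id <- if (spec$us_present) 1 else 0
  d <- dopamine(reward_signal(0, d_id), cfg)
  list(stimulus = stim, delta = d, rewarded = is_rewarded(d))
}
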