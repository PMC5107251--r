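# Simulated VTA dopaminergic reward signal.
#
# Each perceived state carries a scalar "ideal degree" (ID) rating how
# favourable it is.  The reward for an executed action chain is a sigmoid of
# the change in ideal degree, R = 2/(1 + e^-dID) - 1, an odd, strictly
# increasing function with range (-1, 1).  The dopamine signal is
# delta = k * (R - R'), with the reward prediction R' fixed at 0: the
# simulated agents hold no reward expectations.

#' Dopaminergic gain configuration
#'
#' @param k Positive gain on the reward signal (default 1).
#' @param r_prime Predicted reward, fixed at 0 for all experiments here; the
#'   general prediction-error form `k * (R - r_prime)` is implemented for
#'   completeness.
#' @return A list of class `dopamine_config`.
#' @export
dopamine_config <- function(k = 1, r_prime = 0) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  structure(list(k = k, r_prime = r_prime), class = "dopamine_config")
}

#' Reward as a sigmoid of the ideal-degree change
#'
#' `R = 2/(1 + e^-(id_after - id_before)) - 1`; odd, strictly increasing,
#' bounded in (-1, 1), and 0 when the state's ideal degree does not change.
#'
#' @param id_before,id_after Ideal degrees of the state before and after the
#'   action chain.
#' @return The reward value, strictly inside (-1, 1) for finite inputs.
#' @export
reward_signal <- function(id_before, id_after) {
  2 / (1 + exp(-(id_after - id_before))) - 1
}

#' Dopamine signal
#'
#' @param R Reward value from [reward_signal()].
#' @param cfg A [dopamine_config()].
#' @return `k * (R - r_prime)`.
#' @export
dopamine <- function(R, cfg = dopamine_config()) {
  cfg$k * (R - cfg$r_prime)
}

#' Is a dopamine signal rewarding?
#'
#' Strictly positive dopamine counts as reward; zero (no change in ideal
#' degree) and negative signals count as no reward.
#'
#' @param delta Dopamine value(s).
#' @return Logical, vectorized.
#' @export
is_rewarded <- function(delta) {
  delta > 0
}
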