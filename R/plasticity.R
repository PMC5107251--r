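# Count-based log-odds plasticity.
#
# Every plastic synapse keeps two tallies: nr, the number of times the action
# chain through it was rewarded, and nbar, the number of times it was not.
# The synaptic weight is the log likelihood ratio w = ln(nr/nbar).  One
# outcome changes w by the incremental forms
#     rewarded:   w <- w + ln(1 + (1 + e^-w)/(nr + nbar))
#     unrewarded: w <- w - ln(1 + (1 + e^ w)/(nr + nbar))
# evaluated at the PRE-update totals, after which the matching count is
# incremented.  Under pseudocount initialization (nr = nbar = 1, w = 0) this
# incremental form coincides exactly with the closed count-ratio form at
# every step, which the tests audit to 1e-9.

# Single code path for every synapse update (scalar EdgeStats and the
# network's weight banks both route through here).
plasticity_step <- function(nr, nbar, w, rewarded, mode = "canonical", mu = 0.1) {
  if (mode == "canonical") {
    if (rewarded) {
      w <- w + log1p((1 + exp(-w)) / (nr + nbar))
      nr <- nr + 1
    } else {
      w <- w - log1p((1 + exp(w)) / (nr + nbar))
      nbar <- nbar + 1
    }
  } else if (mode == "raw") {
    # sensitivity mode: counts start at 0; the outcome count is incremented
    # first and the denominator floored at 1 so the first update is defined
    if (rewarded) nr <- nr + 1 else nbar <- nbar + 1
    denom <- max(nr + nbar, 1)
    w <- if (rewarded) w + log1p((1 + exp(-w)) / denom)
         else          w - log1p((1 + exp(w)) / denom)
  } else if (mode == "asymptotic") {
    # large-count limit with a fixed learning rate mu
    w <- w + asymptotic_delta(w, mu, rewarded)
    if (rewarded) nr <- nr + 1 else nbar <- nbar + 1
  } else {
    stop("unknown update mode: ", mode, call. = FALSE)
  }
  list(nr = nr, nbar = nbar, w = w)
}

#' Create a plastic synapse (edge statistic)
#'
#' An `edge_stat` bundles the reward count `nr`, the no-reward count `nbar`
#' and the synaptic weight `w`.  In the default `"canonical"` mode both
#' counts start at the pseudocount 1 so that `w = ln(nr/nbar) = 0` before any
#' learning, and the log-odds identity holds exactly after every update.
#'
#' @param nr,nbar Initial counts.  Must be at least 1 in canonical mode
#'   (pseudocounts included); at least 0 in `"raw"` mode.
#' @param mode `"canonical"` (pseudocount log-odds, the default), `"raw"`
#'   (counts start at 0, denominator floored at 1 after the increment), or
#'   `"asymptotic"` (fixed learning rate, see [asymptotic_delta()]).
#' @param w Initial weight.  Defaults to `ln(nr/nbar)` in canonical mode and
#'   0 otherwise.
#' @return An object of class `edge_stat` with fields `nr`, `nbar`, `w`,
#'   `mode`.
#' @seealso [update_rewarded()], [update_unrewarded()]
#' @examples
#' e <- edge_stat()
#' e <- update_rewarded(e)
#' e$w  # ln(2)
#' @export
edge_stat <- function(nr = 1, nbar = 1, mode = c("canonical", "raw", "asymptotic"),
                      w = NULL) {
  mode <- match.arg(mode)
  if (mode == "canonical") {
    if (nr < 1 || nbar < 1) {
      stop("canonical mode requires nr >= 1 and nbar >= 1 (pseudocounts)",
           call. = FALSE)
    }
    w <- w %||% log(nr / nbar)
    if (abs(w - log(nr / nbar)) > 1e-9) {
      stop("canonical edge_stat requires w = ln(nr/nbar)", call. = FALSE)
    }
  } else {
    if (nr < 0 || nbar < 0) stop("counts must be non-negative", call. = FALSE)
    w <- w %||% 0
  }
  structure(list(nr = nr, nbar = nbar, w = w, mode = mode),
            class = "edge_stat")
}

#' @export
print.edge_stat <- function(x, ...) {
  cat(sprintf("<edge_stat %s> nr = %g, nbar = %g, w = %.6f\n",
              x$mode, x$nr, x$nbar, x$w))
  invisible(x)
}

#' Apply one rewarded / unrewarded outcome to a synapse
#'
#' `update_rewarded` applies the weight increment
#' `w + ln(1 + (1 + e^-w)/(nr + nbar))` (computed from the pre-update totals)
#' and then increments `nr`; `update_unrewarded` applies the mirrored
#' decrement and increments `nbar`.  In canonical mode the result always
#' equals `ln(nr/nbar)` of the updated counts.
#'
#' @param e An [edge_stat()].
#' @param mu Learning rate, used only in `"asymptotic"` mode.
#' @return The updated `edge_stat`.
#' @export
update_rewarded <- function(e, mu = 0.1) {
  s <- plasticity_step(e$nr, e$nbar, e$w, TRUE, e$mode, mu)
  e[c("nr", "nbar", "w")] <- s
  e
}

#' @rdname update_rewarded
#' @export
update_unrewarded <- function(e, mu = 0.1) {
  s <- plasticity_step(e$nr, e$nbar, e$w, FALSE, e$mode, mu)
  e[c("nr", "nbar", "w")] <- s
  e
}

#' Asymptotic (large-count) weight change
#'
#' In the limit of many observations, `1/(nr + nbar)` plays the role of a
#' learning rate mu and one outcome changes the weight by
#' `mu * (1 + e^-w)` when rewarded and `-mu * (1 + e^w)` when not.
#'
#' @param w Current weight(s).
#' @param mu Positive learning rate.
#' @param rewarded Logical: was the outcome rewarded?
#' @return The weight change (vectorized over `w`).
#' @export
asymptotic_delta <- function(w, mu, rewarded) {
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  ifelse(rewarded, mu * (1 + exp(-w)), -mu * (1 + exp(w)))
}

#' Expected asymptotic weight change under Bernoulli reward
#'
#' With reward probability `p` the expected one-step change is
#' `p * mu * (1 + e^-w) - (1 - p) * mu * (1 + e^w)`.  It vanishes exactly at
#' the log-odds weight `w = ln(p/(1-p))`, which is the rule's stationary
#' point: the weight estimates the log likelihood ratio of reward.
#'
#' @param w Weight(s).
#' @param p Reward probability, strictly inside (0, 1).
#' @param mu Positive learning rate.
#' @return Expected weight change (vectorized over `w` and `p`).
#' @export
expected_delta <- function(w, p, mu) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  p * mu * (1 + exp(-w)) - (1 - p) * mu * (1 + exp(w))
}

#' Stationary weight for a given reward probability
#'
#' The unique root in `w` of [expected_delta()]: `ln(p/(1-p))`.
#'
#' @param p Reward probability, strictly inside (0, 1).
#' @return The log-odds weight at which learning stops changing on average.
#' @export
stationary_weight <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  log(p / (1 - p))
}
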