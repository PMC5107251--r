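# The working-memory -> action network.
#
# Working-memory neurons feed the first action layer through a full bipartite
# bank of plastic synapses; each further action layer is fully connected to
# the previous one.  Each layer is one step of action selection, so a
# depth-L network expresses action chains of length L.  Non-last-layer
# neurons are linear (ADALINE-style); last-layer neurons are perceptron
# units with a shared threshold b.

new_bank <- function(nrow, ncol, mode) {
  init <- if (mode == "raw") 0 else 1
  list(nr   = matrix(init, nrow, ncol),
       nbar = matrix(init, nrow, ncol),
       w    = matrix(0, nrow, ncol))
}

#' Construct a layered action network
#'
#' @param n_wm Number of working-memory neurons.
#' @param actions First-layer actions: a character vector of labels, or a
#'   single count (labels default to `a1, a2, ...`).
#' @param wm_labels Optional labels for the working-memory neurons.
#' @param threshold_b Threshold (bias) of the last-layer perceptron neurons;
#'   `-Inf` makes every last-layer neuron fire whenever driven.
#' @param mode Plasticity mode for every synapse, see [edge_stat()].
#' @return An object of class `action_network` with fields `n_wm`,
#'   `wm_labels`, `layers` (list of per-layer action labels), `banks` (one
#'   weight bank per layer: matrices `nr`, `nbar`, `w`; bank 1 is
#'   working-memory x layer-1, bank L is layer-(L-1) x layer-L),
#'   `threshold_b` and `mode`.
#' @examples
#' net <- action_network(1, c("a1", "a2"), threshold_b = -Inf)
#' net <- add_layer(net, 2)
#' n_edges(net)  # 2 + 4
#' @export
action_network <- function(n_wm, actions, wm_labels = NULL, threshold_b = 0,
                           mode = c("canonical", "raw", "asymptotic")) {
  mode <- match.arg(mode)
  if (is.numeric(actions) && length(actions) == 1) {
    actions <- paste0("a", seq_len(actions))
  }
  n_wm <- as.integer(n_wm)
  stopifnot(n_wm >= 1, length(actions) >= 1)
  wm_labels <- wm_labels %||% paste0("wm", seq_len(n_wm))
  stopifnot(length(wm_labels) == n_wm)
  net <- structure(
    list(n_wm = n_wm, wm_labels = wm_labels,
         layers = list(actions),
         banks = list(new_bank(n_wm, length(actions), mode)),
         threshold_b = threshold_b, mode = mode),
    class = "action_network")
  validate_action_network(net)
}

validate_action_network <- function(net) {
  stopifnot(length(net$layers) == length(net$banks))
  for (L in seq_along(net$layers)) {
    m <- length(net$layers[[L]])
    if (m < 1) stop("layer ", L, " is empty", call. = FALSE)
    prev <- if (L == 1) net$n_wm else length(net$layers[[L - 1]])
    b <- net$banks[[L]]
    if (!identical(dim(b$w), c(prev, m)) ||
        !identical(dim(b$nr), c(prev, m)) ||
        !identical(dim(b$nbar), c(prev, m))) {
      stop("bank ", L, " has wrong dimensions", call. = FALSE)
    }
    if (net$mode == "canonical" &&
        max(abs(b$w - log(b$nr / b$nbar))) > 1e-9) {
      stop("bank ", L, " violates w = ln(nr/nbar)", call. = FALSE)
    }
  }
  net
}

#' @export
print.action_network <- function(x, ...) {
  cat(sprintf("<action_network> %d working-memory neuron(s) -> %s; b = %s, mode = %s\n",
              x$n_wm,
              paste(vapply(x$layers, length, 0L), collapse = " -> "),
              format(x$threshold_b), x$mode))
  invisible(x)
}

#' Linear neuron output
#'
#' The inner product `u(t) = sum_i w_i x_i(t)` of a weight vector with a
#' stimulus vector.
#'
#' @param weights,inputs Numeric vectors of equal length.
#' @return The scalar drive `u(t)`.
#' @export
linear_output <- function(weights, inputs) {
  if (length(weights) != length(inputs)) {
    stop("weights and inputs must have equal length", call. = FALSE)
  }
  sum(weights * inputs)
}

#' Perceptron threshold output
#'
#' Fires (returns 1) when the drive reaches the threshold: `u >= b`, and the
#' boundary `u == b` fires.
#'
#' @param u Drive value(s).
#' @param b Threshold (bias).
#' @return 0/1, vectorized over `u`.
#' @export
threshold_output <- function(u, b) {
  as.integer(u >= b)
}

#' Append an action layer to the network
#'
#' When learning stalls (no reward within the growth budget), the action
#' chain is deemed too short and a new layer is appended after the current
#' last layer.  The new layer gets one neuron per selectable action and a
#' fresh, pseudocount-initialized weight bank from the previous last layer;
#' all existing synapses are untouched.
#'
#' @param net An [action_network()].
#' @param n_actions Number of neurons (selectable actions) in the new layer.
#' @param labels Optional labels; default `a1, a2, ...`.
#' @return The grown network.
#' @export
add_layer <- function(net, n_actions, labels = NULL) {
  stopifnot(n_actions >= 1)
  labels <- labels %||% paste0("a", seq_len(n_actions))
  stopifnot(length(labels) == n_actions)
  prev <- length(net$layers[[length(net$layers)]])
  net$layers <- c(net$layers, list(labels))
  net$banks <- c(net$banks, list(new_bank(prev, n_actions, net$mode)))
  validate_action_network(net)
}

#' Total number of plastic synapses
#' @param net An [action_network()].
#' @return Integer count over all weight banks.
#' @export
n_edges <- function(net) {
  sum(vapply(net$banks, function(b) length(b$w), 0))
}

#' Flatten all synaptic weights to a named vector
#'
#' Bank-1 entries are named `w_<wm label>_<action>`; deeper banks
#' `w<L>_<previous action>_<action>`.
#'
#' @param net An [action_network()].
#' @return Named numeric vector of every weight.
#' @export
flatten_weights <- function(net) {
  out <- numeric(0)
  for (L in seq_along(net$banks)) {
    b <- net$banks[[L]]
    rown <- if (L == 1) net$wm_labels else net$layers[[L - 1]]
    coln <- net$layers[[L]]
    nm <- outer(rown, coln, function(i, j) {
      if (L == 1) paste0("w_", i, "_", j) else paste0("w", L, "_", i, "_", j)
    })
    v <- as.vector(b$w)
    names(v) <- as.vector(nm)
    out <- c(out, v)
  }
  out
}

#' Apply one trial outcome to every synapse along an executed chain
#'
#' Each working-memory input synapse onto the chosen first-layer action, and
#' each interlayer synapse between consecutively chosen actions, receives
#' the same rewarded/unrewarded outcome.
#'
#' @param net An [action_network()].
#' @param seq_idx Integer vector, one chosen neuron index per layer
#'   (as returned by [select_sequence()]).
#' @param rewarded Logical outcome of the trial.
#' @param mu Learning rate for `"asymptotic"` mode.
#' @return The updated network.
#' @export
update_chain <- function(net, seq_idx, rewarded, mu = 0.1) {
  stopifnot(length(seq_idx) == length(net$banks))
  bank_step <- function(bank, i, j) {
    s <- plasticity_step(bank$nr[i, j], bank$nbar[i, j], bank$w[i, j],
                         rewarded, net$mode, mu)
    bank$nr[i, j] <- s$nr
    bank$nbar[i, j] <- s$nbar
    bank$w[i, j] <- s$w
    bank
  }
  for (j in seq_len(net$n_wm)) {
    net$banks[[1]] <- bank_step(net$banks[[1]], j, seq_idx[1])
  }
  for (L in seq_along(seq_idx)[-1]) {
    net$banks[[L]] <- bank_step(net$banks[[L]], seq_idx[L - 1], seq_idx[L])
  }
  net
}
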