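# Three-store memory: one-slot sensory buffer, working-memory stimulus
# coding, and a JSON long-term store that persists the learned network
# (shape, counts, weights) and per-chain reward tallies between runs.

LTM_SCHEMA_VERSION <- 1L

#' One-slot sensory buffer
#'
#' Holds exactly one raw stimulus snapshot, just long enough to hand it to
#' working memory; no decay dynamics.
#'
#' @return An empty `sensory_buffer`.
#' @export
sensory_buffer <- function() {
  structure(list(latest = NULL, trial_stamp = 0L), class = "sensory_buffer")
}

#' Store a raw observation in the sensory buffer
#'
#' @param buf A [sensory_buffer()].
#' @param obs Raw observation (any R object).
#' @param trial Trial index stamp.
#' @return The buffer with the previous snapshot replaced.
#' @export
buffer_observe <- function(buf, obs, trial) {
  buf$latest <- obs
  buf$trial_stamp <- as.integer(trial)
  buf
}

#' Encode a raw observation as a working-memory stimulus vector
#'
#' Pavlov: two binary presence channels, `bell` (conditioned stimulus) and
#' `food` (unconditioned stimulus).  Thorndike: a single integer state code
#' in 1..3 (hungry, half-hungry, full).
#'
#' @param obs For `"pavlov"`, a list with logical elements `bell` and
#'   `food`; for `"thorndike"`, an integer state (or a list with element
#'   `state`).
#' @param env `"pavlov"` or `"thorndike"`.
#' @return Named numeric stimulus vector, one entry per working-memory
#'   neuron.
#' @export
encode_stimulus <- function(obs, env = c("pavlov", "thorndike")) {
  env <- match.arg(env)
  if (env == "pavlov") {
    if (!is.list(obs) || !all(c("bell", "food") %in% names(obs)) ||
        length(setdiff(names(obs), c("bell", "food"))) > 0) {
      stop("pavlov observation must have exactly the channels 'bell' and 'food'",
           call. = FALSE)
    }
    c(bell = as.numeric(isTRUE(obs$bell) || identical(obs$bell, 1)),
      food = as.numeric(isTRUE(obs$food) || identical(obs$food, 1)))
  } else {
    state <- if (is.list(obs)) obs$state else obs
    if (is.null(state) || length(state) != 1 || !state %in% 1:3) {
      stop("thorndike observation must be a state code in 1, 2, 3",
           call. = FALSE)
    }
    c(wm1 = as.numeric(state))
  }
}

net_to_list <- function(net) {
  list(n_wm = net$n_wm,
       wm_labels = as.list(net$wm_labels),
       layers = lapply(net$layers, as.list),
       # threshold may be -Inf, which JSON cannot carry as a number
       threshold_b = format(net$threshold_b, digits = 17),
       mode = net$mode,
       banks = lapply(net$banks, function(b) {
         list(nrow = nrow(b$w), ncol = ncol(b$w),
              nr = as.vector(b$nr), nbar = as.vector(b$nbar),
              w = as.vector(b$w))
       }))
}

list_to_net <- function(x) {
  banks <- lapply(x$banks, function(b) {
    list(nr   = matrix(as.numeric(b$nr), b$nrow, b$ncol),
         nbar = matrix(as.numeric(b$nbar), b$nrow, b$ncol),
         w    = matrix(as.numeric(b$w), b$nrow, b$ncol))
  })
  net <- structure(
    list(n_wm = as.integer(x$n_wm),
         wm_labels = as.character(unlist(x$wm_labels)),
         layers = lapply(x$layers, function(l) as.character(unlist(l))),
         banks = banks,
         threshold_b = as.numeric(x$threshold_b),
         mode = x$mode),
    class = "action_network")
  validate_action_network(net)
}

#' Save the learning state to the long-term store
#'
#' Writes a single JSON document holding the network shape, every synapse's
#' counts and weight, the per-chain reward tallies and run metadata.  Both
#' counts and weights are stored; their log-odds consistency is re-asserted
#' on load.  Saving is deterministic: equal states give byte-identical
#' files.
#'
#' @param state List with elements `network` (an [action_network()]),
#'   `tallies` (named list of `(R, Rbar)` per chain identity, may be empty)
#'   and optionally `meta` (a list of run metadata).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_long_term()]
#' @export
save_long_term <- function(state, path) {
  stopifnot(inherits(state$network, "action_network"))
  doc <- list(schema_version = LTM_SCHEMA_VERSION,
              network = net_to_list(state$network),
              tallies = state$tallies %||% list(),
              meta = state$meta %||% list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load the learning state from the long-term store
#'
#' If the file is missing, `default` is returned (typically `NULL`, meaning
#' the caller initializes a fresh network with all weights 0).  A file that
#' cannot be parsed, has an unknown schema version, or whose weights are
#' inconsistent with their counts raises an explicit error rather than
#' silently reinitializing.
#'
#' @param path Store file path.
#' @param default Value returned when the file does not exist.
#' @return A list with elements `network`, `tallies`, `meta`, or `default`.
#' @export
load_long_term <- function(path, default = NULL) {
  if (!file.exists(path)) return(default)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse long-term store '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(as.integer(doc$schema_version %||% -1L), LTM_SCHEMA_VERSION)) {
    stop("long-term store '", path, "' has unsupported schema version",
         call. = FALSE)
  }
  net <- tryCatch(list_to_net(doc$network),
                  error = function(e) stop("corrupt long-term store '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  tallies <- lapply(doc$tallies, function(t) {
    c(R = as.numeric(t$R %||% t[[1]]), Rbar = as.numeric(t$Rbar %||% t[[2]]))
  })
  list(network = net, tallies = tallies, meta = doc$meta %||% list())
}

# increment the per-chain reward tallies (R / Rbar of working memory)
tally_update <- function(tallies, id, rewarded) {
  if (is.null(tallies[[id]])) tallies[[id]] <- c(R = 0, Rbar = 0)
  which <- if (rewarded) "R" else "Rbar"
  tallies[[id]][which] <- tallies[[id]][which] + 1
  tallies
}
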