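# Run configuration, config-file parsing and trial-log output.

#' Experiment run configuration
#'
#' Collects every tunable of the simulated conditioning experiments with the
#' defaults the experiments use: 50 acquisition and 50 extinction trials, a
#' 30-trial single-action phase and a 100-trial sequence phase, unit
#' dopamine gain, entropy stop at 0.3 nats, first-index tie-breaking.
#'
#' @param env `"pavlov"` or `"thorndike"`.
#' @param acquisition_trials,extinction_trials Pavlov phase lengths.
#' @param phase1_trials Trial cap of the Thorndike single-action phase
#'   (30 by default, matching the growth budget so the layer is added at its
#'   end).  0 skips the phase: the network starts with two layers.
#' @param phase2_trials Trial cap of the sequence-learning phase.
#' @param b_grid_acquisition Thresholds swept for the salivation probe in
#'   acquisition: 11 values 2.5, 2.8, ..., 5.5.
#' @param b_grid_extinction Thresholds swept in extinction: 12 values
#'   1.0, 1.3, ..., 4.3.
#' @param update_mode Plasticity mode, see [edge_stat()].
#' @param mu Learning rate for `"asymptotic"` mode.
#' @param policy A [policy_config()].
#' @param dopamine A [dopamine_config()].
#' @param max_layers Cap on network depth under growth (default 2, the
#'   depth the puzzle-box task needs).
#' @param persist_state Should the puzzle-box satiety state carry over from
#'   one trial to the next?  Default `FALSE`: every trial starts hungry.
#' @param seed Optional integer seed; set once at the start of a run.
#' @param ltm Optional path of the long-term store to load/save.
#' @param initial_counts Optional extinction initialization when no store is
#'   given: a list with numeric `(nr, nbar)` pairs named after the
#'   working-memory channels, e.g. `list(bell = c(51, 1), food = c(51, 1))`.
#' @param out_dir Optional output directory for the CLI.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(env = c("pavlov", "thorndike"),
                       acquisition_trials = 50L,
                       extinction_trials = 50L,
                       phase1_trials = 30L,
                       phase2_trials = 100L,
                       b_grid_acquisition = seq(2.5, 5.5, by = 0.3),
                       b_grid_extinction = seq(1.0, by = 0.3, length.out = 12),
                       update_mode = c("canonical", "raw", "asymptotic"),
                       mu = 0.1,
                       policy = policy_config(),
                       dopamine = dopamine_config(),
                       max_layers = 2L,
                       persist_state = FALSE,
                       seed = NULL,
                       ltm = NULL,
                       initial_counts = NULL,
                       out_dir = NULL) {
  env <- match.arg(env)
  update_mode <- match.arg(update_mode)
  if (acquisition_trials < 1 || extinction_trials < 1 || phase2_trials < 1) {
    stop("trial counts must be >= 1", call. = FALSE)
  }
  if (phase1_trials < 0) stop("phase1_trials must be >= 0", call. = FALSE)
  if (max_layers < 1) stop("max_layers must be >= 1", call. = FALSE)
  stopifnot(is.numeric(b_grid_acquisition), length(b_grid_acquisition) >= 1,
            is.numeric(b_grid_extinction), length(b_grid_extinction) >= 1,
            inherits(policy, "policy_config"),
            inherits(dopamine, "dopamine_config"))
  structure(list(env = env,
                 acquisition_trials = as.integer(acquisition_trials),
                 extinction_trials = as.integer(extinction_trials),
                 phase1_trials = as.integer(phase1_trials),
                 phase2_trials = as.integer(phase2_trials),
                 b_grid_acquisition = b_grid_acquisition,
                 b_grid_extinction = b_grid_extinction,
                 update_mode = update_mode, mu = mu,
                 policy = policy, dopamine = dopamine,
                 max_layers = as.integer(max_layers),
                 persist_state = isTRUE(persist_state),
                 seed = seed, ltm = ltm,
                 initial_counts = initial_counts, out_dir = out_dir),
            class = "run_config")
}

#' Parse a YAML or JSON run-configuration file
#'
#' Top-level keys mirror the [run_config()] arguments; `policy` and
#' `dopamine` are nested maps mirroring [policy_config()] and
#' [dopamine_config()].  An empty file yields all defaults; unknown keys and
#' out-of-range values raise named validation errors.
#'
#' @param path Config file; `.json` is parsed as JSON, anything else as
#'   YAML.
#' @return A [run_config()].
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- raw %||% list()
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)
  top <- setdiff(names(formals(run_config)), c("policy", "dopamine"))
  unknown <- setdiff(names(raw), c(top, "policy", "dopamine"))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_nested <- function(x, fn, what) {
    x <- x %||% list()
    bad <- setdiff(names(x), names(formals(fn)))
    if (length(bad)) {
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    do.call(fn, x)
  }
  args <- raw[intersect(names(raw), top)]
  args$policy <- check_nested(raw$policy, policy_config, "policy")
  args$dopamine <- check_nested(raw$dopamine, dopamine_config, "dopamine")
  do.call(run_config, args)
}

new_trial_log <- function(df, config, events = character(0)) {
  structure(list(trials = df, config = config, events = events),
            class = "trial_log")
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("<trial_log> %s: %d trial(s)\n", x$config$env, nrow(x$trials)))
  if (nrow(x$trials)) print(utils::tail(x$trials, 3))
  invisible(x)
}

#' Write a trial log as CSV
#'
#' Stable column order, header row, floating-point values at 9 significant
#' digits; identical logs give byte-identical files.
#'
#' @param log A `trial_log` as returned by the `run_*` functions (a plain
#'   data.frame is also accepted).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  df <- if (inherits(log, "trial_log")) log$trials else log
  stopifnot(is.data.frame(df))
  is_dbl <- vapply(df, is.double, TRUE)
  df[is_dbl] <- lapply(df[is_dbl], function(x) format(x, digits = 9, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
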