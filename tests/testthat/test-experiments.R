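test_that("acquisition: weight follows ln(1+t), concave, with the b sweep ordered", {
  log <- run_acquisition(run_config("pavlov"))
  df <- log$trials
  expect_equal(nrow(df), 50)
  expect_equal(df$w_bell_salivate, log(1 + 1:50), tolerance = 1e-9)
  expect_true(all(diff(df$w_bell_salivate) > 0))
  expect_true(all(diff(diff(df$w_bell_salivate)) < 0))  # shrinking increments
  expect_equal(df$w_food_salivate, df$w_bell_salivate)
  # smaller thresholds fire earlier on the bell-alone probe
  grid <- run_config("pavlov")$b_grid_acquisition
  expect_length(grid, 11)
  expect_equal(range(grid), c(2.5, 5.5))
  first_fire <- vapply(grid, function(b) {
    hit <- which(df[[paste0("out_b", format(b))]] == 1)
    if (length(hit)) hit[1] else nrow(df) + 1  # never fired in the horizon
  }, 0)
  expect_true(all(diff(first_fire) >= 0))
  expect_lt(first_fire[1], first_fire[6])
})

test_that("extinction: weight follows ln(51/(1+t)); bigger b extinguishes sooner", {
  cfg <- run_config("pavlov",
                    initial_counts = list(bell = c(51, 1), food = c(51, 1)))
  df <- run_extinction(cfg)$trials
  expect_equal(df$w_bell_salivate, log(51 / (1 + 1:50)), tolerance = 1e-9)
  expect_true(all(diff(df$w_bell_salivate) < 0))
  grid <- cfg$b_grid_extinction
  expect_length(grid, 12)
  expect_equal(grid[1], 1.0)
  expect_equal(diff(grid)[1], 0.3)
  last_fire <- vapply(grid, function(b) {
    off <- which(df[[paste0("out_b", format(b))]] == 0)
    if (length(off)) off[1] else nrow(df) + 1
  }, 0)
  expect_true(all(diff(last_fire) <= 0))
  expect_error(run_extinction(run_config("pavlov")), "prior learning")
})

test_that("single-action phase: weights only decay and choices alternate", {
  log <- run_thorndike(run_config("thorndike"))
  p1 <- log$trials[log$trials$phase == 1, ]
  expect_equal(nrow(p1), 30)
  expect_false(any(p1$rewarded))
  expect_equal(p1$sequence, rep(c("a1", "a2"), 15))
  expect_true(all(diff(p1$w_wm1_a1) <= 0))
  expect_true(all(diff(p1$w_wm1_a2) <= 0))
  expect_equal(p1$event[30], "grow")
  expect_equal(p1$w_wm1_a1[30], log(1 / 16), tolerance = 1e-9)
})

test_that("sequence phase: two early errors, then the rewarded chain forever", {
  log <- run_thorndike(run_config("thorndike"))
  p2 <- log$trials[log$trials$phase == 2, ]
  expect_equal(p2$sequence[1:2], c("a1a1", "a2a1"))
  expect_true(all(p2$sequence[-(1:2)] == "a1a2"))
  expect_true(all(p2$rewarded[-(1:2)]))
  # only the synapses on the rewarded chain strengthen; the never-again
  # selected ones freeze
  last <- p2[nrow(p2), ]
  expect_true(all(diff(p2$w_wm1_a1[-(1:2)]) > 0))  # recovering from decay
  expect_gt(last$`w2_a1_a2`, log(2))
  expect_equal(last$`w2_a2_a2`, 0)
  expect_equal(last$`w2_a2_a1`, log(1 / 2), tolerance = 1e-9)
  expect_true(all(diff(p2$`w2_a1_a2`[-(1:2)]) > 0))
  expect_equal(p2$event[nrow(p2)], "stop")
  # entropy stop matches the counts-based oracle
  expect_equal(nrow(p2), entropy_crossing_trial(0.3, errors = 2))
})

test_that("every logged weight matches ln(nr/nbar) of the final network", {
  path <- withr::local_tempfile(fileext = ".json")
  cfg <- run_config("thorndike")
  cfg$ltm <- path
  log <- run_thorndike(cfg)
  st <- load_long_term(path)
  for (b in st$network$banks) {
    expect_equal(b$w, log(b$nr / b$nbar), tolerance = 1e-9)
  }
  final <- flatten_weights(st$network)
  last_row <- log$trials[nrow(log$trials), names(final)]
  expect_equal(unlist(last_row), final, tolerance = 1e-12)
})

test_that("persisted experience makes successive runs stop sooner", {
  cfg <- run_config("thorndike")
  res <- run_repeated_thorndike(cfg, n_runs = 10)
  expect_length(res$trials_to_stop, 10)
  expect_true(all(diff(res$trials_to_stop) <= 0))
  # later runs begin with the trained two-layer network
  expect_true(all(res$logs[[2]]$trials$phase == 2))
  expect_true(all(res$logs[[2]]$trials$sequence == "a1a2"))
  # without persistence the task is relearned identically each time
  fresh <- replicate(3, nrow(run_thorndike(run_config("thorndike"))$trials))
  expect_equal(length(unique(fresh)), 1)
})

test_that("phase1_trials = 0 starts the sequence phase from zero weights", {
  cfg <- run_config("thorndike", phase1_trials = 0)
  log <- run_thorndike(cfg)
  expect_true(all(log$trials$phase == 2))
  expect_equal(log$trials$sequence[1:3], c("a1a1", "a2a1", "a1a2"))
})

test_that("persistent satiety saturates and stops paying off", {
  cfg <- run_config("thorndike", phase1_trials = 0, persist_state = TRUE)
  df <- run_thorndike(cfg)$trials
  # two early errors from hungry, then success feeds the agent up to full,
  # after which repeating the chain no longer changes the state
  expect_equal(df$state_after[1:5], c(1, 1, 2, 3, 3))
  expect_equal(df$rewarded[1:5], c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # once full, the chain stops paying off; its weights decay until the
  # agent wanders, the state drops, and reward eventually resumes
  expect_true(any(df$state_after[-(1:5)] < 3))
  expect_true(any(df$rewarded[-(1:5)]))
})

test_that("Rescorla-Wagner baseline follows its closed form", {
  v <- rescorla_wagner(1, alpha = 0.1, lam = 1, v0 = 0)
  expect_equal(v, c(0, 0.1))
  decay <- rescorla_wagner(20, alpha = 0.1, lam = 0, v0 = 1)
  expect_equal(decay, 0.9^(0:20), tolerance = 1e-12)
  long <- rescorla_wagner(500, alpha = 0.1, lam = 1, v0 = 0)
  expect_equal(long[501], 1, tolerance = 1e-12)
  expect_error(rescorla_wagner(10, alpha = 0), "alpha")
  # both models rise in acquisition and fall in extinction
  acq <- run_acquisition(run_config("pavlov"))$trials$w_bell_salivate
  expect_true(all(diff(acq) > 0) &&
              all(diff(rescorla_wagner(50, 0.1, 1, 0)) > 0))
})
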