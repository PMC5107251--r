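test_that("canonical updates match the count-ratio closed form", {
  e <- edge_stat()
  e <- update_rewarded(e)
  expect_equal(e$nr, 2)
  expect_equal(e$w, log(2), tolerance = 1e-12)
  e <- update_rewarded(e)
  expect_equal(e$w, log(3), tolerance = 1e-12)
  e2 <- update_unrewarded(edge_stat())
  expect_equal(e2$nbar, 2)
  expect_equal(e2$w, -log(2), tolerance = 1e-12)
  e3 <- update_unrewarded(edge_stat(nr = 1, nbar = 3))
  expect_equal(e3$w, log(1 / 4), tolerance = 1e-12)
})

test_that("rewarded updates always increase w; unrewarded always decrease it", {
  set.seed(11)
  for (i in 1:50) {
    e <- edge_stat(nr = sample(1:40, 1), nbar = sample(1:40, 1))
    expect_gt(update_rewarded(e)$w, e$w)
    expect_lt(update_unrewarded(e)$w, e$w)
  }
})

test_that("incremental weight equals ln(nr/nbar) after any outcome sequence", {
  set.seed(42)
  for (rep in 1:5) {
    e <- edge_stat()
    outcomes <- runif(1000) < runif(1)
    for (r in outcomes) {
      e <- if (r) update_rewarded(e) else update_unrewarded(e)
    }
    expect_equal(e$nr, 1 + sum(outcomes))
    expect_equal(e$w, log(e$nr / e$nbar), tolerance = 1e-9)
    expect_equal(e$w, count_ratio_w(sum(outcomes), sum(!outcomes)),
                 tolerance = 1e-9)
  }
})

test_that("one-step |dw| shrinks as the total count grows, at fixed w", {
  for (w0 in c(-1.5, 0, 2)) {
    totals <- c(2, 5, 10, 50, 200, 1000)
    dws <- vapply(totals, function(n) {
      log1p((1 + exp(-w0)) / n)
    }, 0)
    expect_true(all(diff(dws) < 0))
    dws_un <- vapply(totals, function(n) log1p((1 + exp(w0)) / n), 0)
    expect_true(all(diff(dws_un) < 0))
  }
})

test_that("asymptotic_delta matches its closed form and the exact increment", {
  expect_equal(asymptotic_delta(0, 0.1, TRUE), 0.2)
  expect_equal(asymptotic_delta(0, 0.1, FALSE), -0.2)
  expect_equal(asymptotic_delta(50, 0.1, TRUE), 0.1, tolerance = 1e-12)
  expect_error(asymptotic_delta(0, -1, TRUE), "positive")
  # agreement with the exact log increment once counts are large:
  # |ln(1+x) - x| <= x^2/2, with x = (1+e^±w)/(nr+nbar)
  for (w0 in c(-1, 0, 1)) {
    for (n in c(100, 400, 2000)) {
      exact <- log1p((1 + exp(-w0)) / n)
      approx <- asymptotic_delta(w0, 1 / n, TRUE)
      expect_lt(abs(exact - approx), 1 / n^2 * (1 + exp(-w0))^2)
      expect_lt(abs(exact - approx), 1e-2)
    }
  }
})

test_that("expected_delta vanishes exactly at the log-odds weight", {
  expect_equal(expected_delta(log(3), 0.75, 0.1), 0, tolerance = 1e-12)
  expect_equal(expected_delta(0, 0.5, 0.7), 0, tolerance = 1e-12)
  expect_equal(expected_delta(0, 0.75, 0.1), 0.1, tolerance = 1e-12)
  expect_error(expected_delta(0, 1.2, 0.1), "strictly in")
})

test_that("stationary_weight agrees with a bisection root and is antisymmetric", {
  expect_equal(stationary_weight(0.5), 0)
  expect_equal(stationary_weight(0.75), log(3), tolerance = 1e-12)
  for (p in c(0.1, 0.3, 0.62, 0.9)) {
    expect_equal(stationary_weight(p), bisect_stationary(p), tolerance = 1e-9)
    expect_equal(stationary_weight(p), -stationary_weight(1 - p))
  }
  expect_error(stationary_weight(0), "strictly in")
})

test_that("weights recover the log-odds of Bernoulli reward probabilities", {
  # shorter in-suite version of the stationarity study (the acceptance test
  # runs the full 20,000-step / 20-replicate version)
  set.seed(7)
  for (p in c(0.2, 0.8)) {
    finals <- replicate(8, {
      e <- edge_stat()
      for (r in runif(4000) < p) {
        e <- if (r) update_rewarded(e) else update_unrewarded(e)
      }
      e$w
    })
    expect_true(mean(abs(finals - stationary_weight(p)) < 0.15) >= 0.75)
  }
})

test_that("raw mode defines the first update and then tracks pure counts", {
  e <- edge_stat(nr = 0, nbar = 0, mode = "raw")
  e <- update_rewarded(e)
  expect_equal(e$nr, 1)
  expect_equal(e$w, log1p(2))  # denominator floored at 1 after the increment
  e <- update_unrewarded(e)
  expect_equal(e$nbar, 1)
  expect_error(edge_stat(nr = 0, nbar = 0, mode = "canonical"), "pseudocount")
})
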