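# Independent oracles used across the suite.

# Root of the expected weight change p*(1+e^-w) = (1-p)*(1+e^w), found by
# bisection (independent of the closed form in the package).
bisect_stationary <- function(p, lo = -50, hi = 50, tol = 1e-12) {
  f <- function(w) p * (1 + exp(-w)) - (1 - p) * (1 + exp(w))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Entropy of cumulative counts when the first `errors` trials each pick a
# distinct wrong sequence and every later trial picks the rewarded one.
entropy_after_errors <- function(t, errors = 2) {
  counts <- c(rep(1, errors), t - errors)
  p <- counts / t
  -sum(p * log(p))
}

# First trial at which that entropy drops below `thr`.
entropy_crossing_trial <- function(thr = 0.3, errors = 2, max_t = 1000) {
  for (t in (errors + 1):max_t) {
    if (entropy_after_errors(t, errors) < thr) return(t)
  }
  NA_integer_
}

# Closed-form count-ratio weight for a canonical edge after k rewarded and
# j unrewarded outcomes from the pseudocount start.
count_ratio_w <- function(k, j) log((1 + k) / (1 + j))
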