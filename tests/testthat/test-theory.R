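test_that("persistent envelope limits and values", {
  expect_equal(persistent_envelope(0, 0.9, x0 = 1.3), 1.3)
  expect_equal(persistent_envelope(c(1, 5, 50), 1, x0 = 0.7),
               rep(0.7, 3))  # line-attractor limit
  expect_equal(persistent_envelope(10, 0.95), exp(-0.5), tolerance = 1e-12)
  expect_error(persistent_envelope(-1, 0.9), ">= 0")
})

test_that("decay-amplify envelope is piecewise exponential and continuous", {
  p <- rate_params(d = 0, a = 0, eps = 0.1, T = 3, x0 = 0.8)
  expect_equal(decay_amplify_envelope(c(0, 1.7, 3), 1.5, p), rep(0.8, 3))
  p <- rate_params(d = 0.05, a = 0.05, eps = 0.1, T = 3, x0 = 1)
  # continuity at t_s from both branches
  expect_equal(decay_amplify_envelope(1.5, 1.5, p),
               decay_amplify_envelope(1.5 + 1e-12, 1.5, p),
               tolerance = 1e-9)
  # matched rates with the input at the midpoint cancel exactly at T
  expect_equal(decay_amplify_envelope(3, 1.5, p), 1, tolerance = 1e-12)
  expect_error(decay_amplify_envelope(1, 4, p), "t_s")
})

test_that("line-attractor minimal coupling matches its bisection oracle", {
  # frozen value for eps = 0.1, T = 3 (g ~ 0.96488)
  expect_equal(line_attractor_min_coupling(0.1, 3), 1 + log(0.9) / 3,
               tolerance = 1e-12)
  expect_equal(round(line_attractor_min_coupling(0.1, 3), 5), 0.96488)
  for (eps in c(0.05, 0.1, 0.3)) for (T in c(2, 6, 20)) {
    g_oracle <- bisect(function(g) exp((g - 1) * T) - (1 - eps), 0, 1)
    expect_equal(line_attractor_min_coupling(eps, T), g_oracle,
                 tolerance = 1e-9)
  }
  # limits: perfect resolution or infinite delay drive g -> 1
  expect_lt(1 - line_attractor_min_coupling(1e-9, 3), 1e-9)
  expect_lt(1 - line_attractor_min_coupling(0.1, 1e7), 1e-6)
})

test_that("timing interval: frozen values, bisection oracle, band edges", {
  p <- rate_params(d = 0.05, a = 0.05, eps = 0.1, T = 3, x0 = 1)
  iv <- timing_interval(p)
  expect_equal(round(c(iv$lo, iv$hi, iv$length), 4),
               c(0.5469, 2.5536, 2.0067))
  # closed forms against bisection on the envelope itself
  for (d in c(0.02, 0.08)) for (a in c(0.03, 0.1)) {
    p <- rate_params(d = d, a = a, eps = 0.1, T = 6, x0 = 1)
    iv <- timing_interval(p)
    endv <- function(ts) decay_amplify_envelope(p$T, ts, p)
    lo_o <- bisect(function(ts) endv(ts) - (1 + p$eps), 0, p$T)
    hi_o <- bisect(function(ts) endv(ts) - (1 - p$eps), 0, p$T)
    expect_equal(iv$lo, lo_o, tolerance = 1e-8)
    expect_equal(iv$hi, hi_o, tolerance = 1e-8)
    # envelope sits exactly on the band boundary at the interval ends
    expect_equal(endv(iv$lo), 1 + p$eps, tolerance = 1e-10)
    expect_equal(endv(iv$hi), 1 - p$eps, tolerance = 1e-10)
    # the center balances the band: its log-domain miss is O(eps^2),
    # while the interval ends miss by ~eps
    expect_lt(abs(log(endv(iv$center_raw))), p$eps^2)
    ts_grid <- seq(iv$lo, iv$hi, length.out = 201)
    t_best <- ts_grid[which.min(abs(log(endv(ts_grid))))]
    expect_gte(t_best, iv$lo); expect_lte(t_best, iv$hi)
  }
  expect_error(timing_interval(rate_params(d = 0.05, a = -0.05, eps = 0.1,
                                           T = 3)), "degenerate")
})

test_that("interval length scales as 1/(a + d); approximation -> exact", {
  p1 <- rate_params(d = 0.05, a = 0.05, eps = 0.1, T = 20)
  p2 <- rate_params(d = 0.10, a = 0.10, eps = 0.1, T = 20)
  expect_equal(timing_interval(p1)$length_raw,
               2 * timing_interval(p2)$length_raw, tolerance = 1e-12)
  # frozen example: d = a = 0.05, eps = 0.1 -> approx 2.0, exact 2.0067
  expect_equal(interval_length_approx(p1), 2.0, tolerance = 1e-12)
  # length depends on (d, a) only through the sum
  p3 <- rate_params(d = 0.02, a = 0.08, eps = 0.1, T = 20)
  expect_equal(timing_interval(p1)$length_raw,
               timing_interval(p3)$length_raw, tolerance = 1e-12)
  # ratio approx/exact -> 1 as eps -> 0
  ratios <- vapply(c(1e-1, 1e-2, 1e-3), function(eps) {
    p <- rate_params(d = 0.05, a = 0.05, eps = eps, T = 20)
    interval_length_approx(p) / timing_interval(p)$length_raw
  }, numeric(1))
  expect_true(all(diff(abs(ratios - 1)) < 0))
  expect_lt(abs(ratios[3] - 1), 1e-5)
})

test_that("interval position: a = 0 hugs the start; good tuning needs no input", {
  # no amplification: the input must arrive (essentially) immediately
  p <- rate_params(d = 0.05, a = 0, eps = 0.1, T = 3)
  iv <- timing_interval(p)
  expect_equal(iv$lo, 0)
  expect_lt(iv$center, 0.36 * p$T)
  # coupling at the line-attractor bound: never amplifying still succeeds
  for (T in c(3, 6)) {
    g <- line_attractor_min_coupling(0.1, T)
    p <- rate_params(d = 1 - g, a = 0, eps = 0.1, T = T)
    expect_gte(decay_amplify_envelope(T, T, p), p$x0 * (1 - 0.1) - 1e-12)
  }
})

test_that("amplification_rate and feedback_strength are exact inverses", {
  for (g in c(0.9, 0.95, 0.995)) for (a in c(0.002, 0.05, 0.2)) {
    cfb <- feedback_strength(g, a)
    expect_equal(amplification_rate(g, cfb), a, tolerance = 1e-12)
    # first-order agreement with a = g + c - 1: the correction is O((a+d)^2)
    expect_lt(abs(cfb - (a + (1 - g))), 1.5 * (a + (1 - g))^2)
  }
})

test_that("chain_solution reduces to the initial profile and the envelope", {
  x0 <- c(rep(0.8, 20), rep(0, 10))
  expect_equal(chain_solution(x0, 0.95, 0)[, 1], x0)
  # g = 1: interior of the block is untouched until the trailing front
  sol <- chain_solution(x0, 1, 5)
  expect_equal(sol[15:20, 1], rep(0.8, 6), tolerance = 1e-3)
  # deep cell tracks the envelope within 2%
  sol <- chain_solution(c(rep(1, 100), rep(0, 10)), 0.95, 10)
  expect_equal(sol[80, 1], persistent_envelope(10, 0.95), tolerance = 0.02)
})
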